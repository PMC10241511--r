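#' Cortical timeseries container
#'
#' A `cortical_ts` holds a vertex-by-time matrix of surface BOLD activity on a
#' two-hemisphere mesh together with the subject metadata used downstream
#' (postmenstrual age at scan, sampling interval, per-frame head motion).
#' Vertices are stored in vertex-major order, left hemisphere block first.
#'
#' @param values numeric matrix, vertices x time.
#' @param mesh_id identifier of the mesh the rows refer to.
#' @param subject_id,session_id identifiers.
#' @param age_weeks postmenstrual age at scan, weeks (> 0).
#' @param dataset_tag one of `"dHCP-like"`, `"DBI-like"`, `"synthetic"`.
#' @param tr_seconds sampling interval in seconds.
#' @param fd_series optional per-frame framewise displacement (mm), length
#'   `ncol(values)`.
#' @return an object of class `cortical_ts`.
#' @export
cortical_ts <- function(values, mesh_id = "mesh", subject_id = "sub-01",
                        session_id = "ses-01", age_weeks = NA_real_,
                        dataset_tag = "synthetic", tr_seconds = 1,
                        fd_series = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values)))
    stop_dim("cortical_ts: values contain non-finite entries in frames [%s]",
             paste(which(colSums(!is.finite(values)) > 0), collapse = ", "))
  if (!is.null(fd_series) && length(fd_series) != ncol(values))
    stop_dim("cortical_ts: fd_series length %d != T = %d",
             length(fd_series), ncol(values))
  structure(list(values = values, mesh_id = mesh_id, subject_id = subject_id,
                 session_id = session_id, age_weeks = age_weeks,
                 dataset_tag = dataset_tag, tr_seconds = tr_seconds,
                 fd_series = fd_series),
            class = "cortical_ts")
}

#' @exportS3Method base::print
print.cortical_ts <- function(x, ...) {
  cat(sprintf("<cortical_ts> %s/%s  V=%d  T=%d  TR=%.3gs  age=%.4g wk  [%s]\n",
              x$subject_id, x$session_id, nrow(x$values), ncol(x$values),
              x$tr_seconds, x$age_weeks, x$dataset_tag))
  invisible(x)
}

#' @export
dim.cortical_ts <- function(x) dim(x$values)

#' Subject metadata table
#'
#' Builds the per-scan metadata table keyed by (subject, session). Ages must be
#' strictly positive and keys unique.
#'
#' @param subject_id,session_id character vectors.
#' @param age_weeks postmenstrual ages (weeks).
#' @param dataset_tag dataset label per scan.
#' @param brain_volume_cc,mean_fd optional covariates.
#' @return a `data.frame` of class `subject_table`.
#' @export
subject_table <- function(subject_id, session_id, age_weeks,
                          dataset_tag = "synthetic",
                          brain_volume_cc = NA_real_, mean_fd = NA_real_) {
  stopifnot(length(subject_id) == length(session_id),
            length(subject_id) == length(age_weeks))
  if (any(!is.finite(age_weeks)) || any(age_weeks <= 0))
    stop("subject_table: ages must be strictly positive", call. = FALSE)
  key <- paste(subject_id, session_id, sep = "/")
  if (anyDuplicated(key))
    stop_dim("subject_table: duplicate (subject, session) keys: %s",
             paste(unique(key[duplicated(key)]), collapse = ", "))
  out <- data.frame(subject_id = subject_id, session_id = session_id,
                    age_weeks = age_weeks, dataset_tag = dataset_tag,
                    brain_volume_cc = brain_volume_cc, mean_fd = mean_fd,
                    stringsAsFactors = FALSE)
  class(out) <- c("subject_table", "data.frame")
  out
}

## ------------------------------------------------------------------------
## internal container: <path> holds raw little-endian doubles, <path>.json the
## dimensions and metadata. Round trips are bit exact.

#' Write a cortical timeseries to the internal container format
#'
#' The container is a flat binary file of little-endian doubles (column-major,
#' vertices fastest) with a JSON sidecar `<path>.json` describing dimensions and
#' metadata. Round trips through [read_surface_timeseries()] are bit identical.
#'
#' @param ts a `cortical_ts`.
#' @param path file path (sidecar written at `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
write_surface_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "cortical_ts"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(ts$values), con, size = 8, endian = "little")
  meta <- list(schema = "latentcortex-ts", schema_version = 1L,
               V = nrow(ts$values), T = ncol(ts$values),
               mesh_id = ts$mesh_id, subject_id = ts$subject_id,
               session_id = ts$session_id, age_weeks = ts$age_weeks,
               dataset_tag = ts$dataset_tag, tr_seconds = ts$tr_seconds,
               fd_series = ts$fd_series)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

read_internal_ts <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_dim("internal container: missing JSON sidecar '%s'", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$schema, "latentcortex-ts"))
    stop_dim("internal container: unexpected schema '%s' in sidecar", meta$schema)
  n <- meta$V * meta$T
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(vals) != n)
    stop_dim("internal container: expected %d doubles, file holds %d", n, length(vals))
  cortical_ts(matrix(vals, meta$V, meta$T), mesh_id = meta$mesh_id,
              subject_id = meta$subject_id, session_id = meta$session_id,
              age_weeks = meta$age_weeks %||% NA_real_,
              dataset_tag = meta$dataset_tag, tr_seconds = meta$tr_seconds,
              fd_series = meta$fd_series)
}

#' Read a surface fMRI timeseries
#'
#' Reads vertex x time functional data into a [cortical_ts()]. Supported
#' formats: `"internal"` (the package's binary container, see
#' [write_surface_timeseries()]) and `"gifti_func"` (GIFTI `.func.gii`, one
#' DataArray per frame or one 2-D DataArray; ASCII, Base64Binary and
#' GZipBase64Binary encodings). CIFTI-2 dense timeseries are not parsed by this
#' package and requesting `"cifti_dtseries"` raises an informative error.
#'
#' @param path file path.
#' @param format one of `"internal"`, `"gifti_func"`, `"cifti_dtseries"`.
#' @param expected_vertices optional vertex count to validate against.
#' @param ... metadata fields passed to [cortical_ts()] for formats that do not
#'   carry them (e.g. `age_weeks` for GIFTI files).
#' @return a `cortical_ts` with left-hemisphere vertices before right.
#' @export
read_surface_timeseries <- function(path,
                                    format = c("internal", "gifti_func",
                                               "cifti_dtseries"),
                                    expected_vertices = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_dim("file not found: '%s'", path)
  ts <- switch(format,
    internal = read_internal_ts(path),
    gifti_func = {
      vals <- read_gifti_data(path)
      cortical_ts(vals, ...)
    },
    cifti_dtseries = stop(paste0(
      "CIFTI-2 dense timeseries parsing (NIfTI-2 container + BrainModel XML ",
      "extension) is not implemented; convert to GIFTI .func.gii per ",
      "hemisphere or to the internal container first"), call. = FALSE))
  bad <- which(colSums(!is.finite(ts$values)) > 0)
  if (length(bad))
    stop_dim("'%s': non-finite values in frame(s) [%s]", path,
             paste(bad, collapse = ", "))
  if (!is.null(expected_vertices) && nrow(ts$values) != expected_vertices)
    stop_dim("'%s': vertex count %d does not match mesh vertex count %d",
             path, nrow(ts$values), expected_vertices)
  ts
}

## Minimal GIFTI reading/writing: GIFTI is XML; numeric payloads are ASCII or
## (GZip)Base64Binary little-endian arrays.

decode_gifti_array <- function(node) {
  enc <- xml2::xml_attr(node, "Encoding")
  dtype <- xml2::xml_attr(node, "DataType")
  dims <- as.integer(c(xml2::xml_attr(node, "Dim0"), xml2::xml_attr(node, "Dim1")))
  dims <- dims[!is.na(dims)]
  data_node <- xml2::xml_find_first(node, ".//Data")
  txt <- xml2::xml_text(data_node)
  vals <- switch(enc,
    ASCII = as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1]]),
    Base64Binary = ,
    GZipBase64Binary = {
      raw <- jsonlite::base64_dec(gsub("[[:space:]]", "", txt))
      if (enc == "GZipBase64Binary") raw <- memDecompress(raw, type = "gzip")
      size <- switch(dtype, NIFTI_TYPE_FLOAT32 = 4L, NIFTI_TYPE_FLOAT64 = 8L,
                     NIFTI_TYPE_INT32 = 4L,
                     stop_dim("GIFTI: unsupported DataType '%s'", dtype))
      what <- if (dtype == "NIFTI_TYPE_INT32") "integer" else "double"
      readBin(raw, what, n = length(raw) %/% size, size = size,
              endian = "little")
    },
    stop_dim("GIFTI: unsupported Encoding '%s'", enc))
  n_expect <- prod(dims)
  if (length(vals) != n_expect)
    stop_dim("GIFTI DataArray: decoded %d values, dims promise %d",
             length(vals), n_expect)
  list(values = vals, dims = dims,
       order = xml2::xml_attr(node, "ArrayIndexingOrder"))
}

read_gifti_data <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_dim("GIFTI: malformed XML in '%s': %s",
                                               path, conditionMessage(e)))
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  if (!length(arrays)) stop_dim("GIFTI: no DataArray elements in '%s'", path)
  decoded <- lapply(arrays, decode_gifti_array)
  if (length(decoded) == 1L && length(decoded[[1]]$dims) == 2L) {
    d <- decoded[[1]]
    m <- matrix(d$values, d$dims[1], d$dims[2],
                byrow = identical(d$order, "RowMajorOrder"))
    return(m)  # vertices x time
  }
  nv <- unique(vapply(decoded, function(d) d$dims[1], integer(1)))
  if (length(nv) != 1L)
    stop_dim("GIFTI: DataArrays disagree on vertex count (%s)",
             paste(nv, collapse = ", "))
  vapply(decoded, function(d) d$values, numeric(nv))
}

#' Write a vertex-by-time matrix as GIFTI
#'
#' Writes a minimal `.func.gii` file with one float32 Base64Binary DataArray per
#' frame (the layout produced for a single hemisphere).
#'
#' @param values numeric matrix, vertices x time.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gifti_func <- function(values, path) {
  values <- as.matrix(values)
  arrays <- vapply(seq_len(ncol(values)), function(j) {
    payload <- jsonlite::base64_enc(writeBin(as.numeric(values[, j]), raw(),
                                             size = 4, endian = "little"))
    paste0('<DataArray Intent="NIFTI_INTENT_NONE" DataType="NIFTI_TYPE_FLOAT32" ',
           'ArrayIndexingOrder="RowMajorOrder" Dimensionality="1" Dim0="',
           nrow(values), '" Encoding="Base64Binary" Endian="LittleEndian" ',
           'ExternalFileName="" ExternalFileOffset="">\n<Data>', payload,
           '</Data>\n</DataArray>')
  }, character(1))
  xml <- paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                '<GIFTI Version="1.0" NumberOfDataArrays="', ncol(values),
                '">\n', paste(arrays, collapse = "\n"), '\n</GIFTI>\n')
  writeLines(xml, path)
  invisible(path)
}

## ------------------------------------------------------------------------
## preprocessing

#' Standardize each vertex timeseries
#'
#' Scales every vertex series to zero mean and unit variance using the
#' population convention (divide by `T`). Constant series are mapped to
#' all-zero rather than NaN.
#'
#' @param ts a `cortical_ts` with at least two frames.
#' @return a `cortical_ts` with standardized rows.
#' @export
normalize_timeseries <- function(ts) {
  stopifnot(inherits(ts, "cortical_ts"))
  X <- ts$values
  if (ncol(X) < 2) stop("normalize_timeseries: need T >= 2", call. = FALSE)
  mu <- rowMeans(X)
  Xc <- X - mu
  sd_pop <- sqrt(rowMeans(Xc^2))
  keep <- sd_pop > 1e-12
  Xc[keep, ] <- Xc[keep, , drop = FALSE] / sd_pop[keep]
  Xc[!keep, ] <- 0
  ts$values <- Xc
  ts
}

#' Remove a per-vertex polynomial trend
#'
#' Regresses out a polynomial of the given order (default cubic, the standard
#' drift model for long acquisitions) from every vertex series and returns the
#' residuals.
#'
#' @param ts a `cortical_ts`.
#' @param order polynomial order (0 = mean removal).
#' @return detrended `cortical_ts`.
#' @export
detrend_poly <- function(ts, order = 3L) {
  stopifnot(inherits(ts, "cortical_ts"), order >= 0)
  Tn <- ncol(ts$values)
  if (Tn <= order + 1)
    stop_dim("detrend_poly: need T > order + 1 (T=%d, order=%d)", Tn, order)
  tt <- seq_len(Tn)
  B <- if (order == 0) matrix(1, Tn, 1) else cbind(1, stats::poly(tt, order))
  qrB <- qr(B)
  ts$values <- t(qr.resid(qrB, t(ts$values)))
  ts
}

#' Temporal bandpass filter
#'
#' Zero-phase (forward-backward) order-4 Butterworth bandpass applied per
#' vertex. The default resting-state band is 0.01-0.1 Hz.
#'
#' @param ts a `cortical_ts` (uses `tr_seconds` for the sampling rate).
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr_seconds)`.
#' @return filtered `cortical_ts`.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(ts, "cortical_ts"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop_dim("bandpass_filter: need 0 < low (%g) < high (%g) < Nyquist (%g Hz)",
             low_hz, high_hz, nyq)
  bf <- signal::butter(4, c(low_hz, high_hz) / nyq, type = "pass")
  ts$values <- t(apply(ts$values, 1, function(x) signal::filtfilt(bf, x)))
  ts
}

#' Select the lowest-motion frames
#'
#' Returns the temporal indices of the `n_keep` frames with the smallest
#' framewise displacement, in ascending temporal order. Ties are broken in
#' favour of the earlier frame. The dHCP-style default keeps 1400 frames.
#'
#' @param fd_series per-frame framewise displacement (mm).
#' @param n_keep number of frames to keep (default 1400).
#' @return integer vector of frame indices (1-based), ascending.
#' @export
select_low_motion_volumes <- function(fd_series, n_keep = 1400L) {
  if (n_keep > length(fd_series))
    stop_dim("select_low_motion_volumes: n_keep=%d > available frames %d",
             n_keep, length(fd_series))
  ord <- order(fd_series, seq_along(fd_series))  # ties -> earlier frame
  sort(ord[seq_len(n_keep)])
}

#' Drop the first and last frames
#'
#' Removes `n_trim` frames from each end of the series (default 150, guarding
#' against filter edge transients).
#'
#' @param ts a `cortical_ts`.
#' @param n_trim frames to drop at each end.
#' @return trimmed `cortical_ts`.
#' @export
trim_edges <- function(ts, n_trim = 150L) {
  stopifnot(inherits(ts, "cortical_ts"), n_trim >= 0)
  Tn <- ncol(ts$values)
  if (Tn <= 2 * n_trim)
    stop_dim("trim_edges: need T > 2*n_trim (T=%d, n_trim=%d)", Tn, n_trim)
  if (n_trim == 0) return(ts)
  keep <- (n_trim + 1):(Tn - n_trim)
  ts$values <- ts$values[, keep, drop = FALSE]
  if (!is.null(ts$fd_series)) ts$fd_series <- ts$fd_series[keep]
  ts
}
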