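#' Per-frame reconstruction degree
#'
#' The reconstruction degree of a model at time t is the Pearson correlation
#' between the original and reconstructed cortical pattern at t, computed over
#' the analysis mask (medial-wall and unassigned vertices excluded). Frames
#' with zero variance on either side yield `NA` with a warning.
#'
#' @param X,Xhat V x T original and reconstructed matrices.
#' @param mask logical vector of analysis vertices (default all).
#' @return numeric vector of length T with per-frame r in `[-1, 1]`.
#' @export
reconstruction_degree <- function(X, Xhat, mask = NULL) {
  if (!all(dim(X) == dim(Xhat)))
    stop_dim("reconstruction_degree: dim mismatch (%s vs %s)",
             paste(dim(X), collapse = "x"), paste(dim(Xhat), collapse = "x"))
  if (!is.null(mask)) {
    X <- X[mask, , drop = FALSE]
    Xhat <- Xhat[mask, , drop = FALSE]
  }
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Xhat, 2, colMeans(Xhat))
  sx <- sqrt(colSums(Xc^2)); sy <- sqrt(colSums(Yc^2))
  r <- colSums(Xc * Yc) / (sx * sy)
  bad <- sx < 1e-12 | sy < 1e-12
  if (any(bad)) {
    warning(sprintf("reconstruction_degree: %d constant frame(s) -> NA",
                    sum(bad)), call. = FALSE)
    r[bad] <- NA_real_
  }
  pmin(1, pmax(-1, r))
}

#' Fisher-z mean of correlations
#'
#' Averages correlations on the Fisher z scale: `tanh(mean(atanh(r)))`.
#' Values are clipped to +/-(1 - 1e-7) before the transform; missing values
#' are skipped.
#'
#' @param r_values numeric vector of correlations.
#' @return scalar mean correlation.
#' @export
fisher_mean <- function(r_values) {
  r <- r_values[!is.na(r_values)]
  if (!length(r)) stop("fisher_mean: all values missing", call. = FALSE)
  r <- pmin(1 - 1e-7, pmax(-1 + 1e-7, r))
  tanh(mean(atanh(r)))
}

## geodesic Gaussian smoothing weights (sparse, row-normalized); truncated at
## 3.5 kernel sds. geo: dense per-pair graph distances (Inf across hemispheres).
smoothing_weights <- function(geo, fwhm_mm) {
  sigma <- fwhm_mm / 2.355
  cut <- 3.5 * sigma
  idx <- which(geo <= cut & is.finite(geo), arr.ind = TRUE)
  w <- exp(-geo[idx]^2 / (2 * sigma^2))
  Wm <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = w,
                             dims = dim(geo))
  rs <- Matrix::rowSums(Wm)
  Matrix::Diagonal(x = 1 / rs) %*% Wm
}

#' Geodesic Gaussian surface smoothing
#'
#' Smooths each frame on the mesh with a Gaussian kernel of the given FWHM
#' (kernel sd = FWHM / 2.355), using edge-graph shortest-path distances as the
#' geodesic approximation. Row-normalized weights preserve constant fields;
#' `fwhm_mm = 0` is the identity.
#'
#' @param ts a `cortical_ts` (or V x T matrix).
#' @param mesh the `cortical_mesh` the data lives on.
#' @param fwhm_mm kernel full width at half maximum, mm (>= 0).
#' @param geo optional precomputed distance matrix from repeated calls.
#' @return smoothed object of the same type as `ts`.
#' @export
surface_smooth <- function(ts, mesh, fwhm_mm, geo = NULL) {
  if (fwhm_mm < 0) stop("surface_smooth: fwhm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(ts)
  X <- if (inherits(ts, "cortical_ts")) ts$values else ts
  geo <- get_geodesics(mesh, geo)
  Wm <- smoothing_weights(geo, fwhm_mm)
  Xs <- as.matrix(Wm %*% X)
  if (inherits(ts, "cortical_ts")) { ts$values <- Xs; ts } else Xs
}

#' Smoothing-effect profile of a reconstruction
#'
#' For each FWHM on the grid, measures the Fisher-mean spatial similarity
#' between the reconstruction and the explicitly smoothed original. The
#' model's effective smoothing is the FWHM at the similarity peak; a peak on
#' the grid boundary is flagged. The default grid is 1-10 mm in 1 mm steps.
#'
#' @param X,Xhat V x T original and reconstructed matrices.
#' @param mesh the mesh.
#' @param fwhm_grid increasing FWHM values, mm.
#' @param mask analysis-vertex mask passed to [reconstruction_degree()].
#' @param geo optional precomputed geodesic matrix.
#' @return list with `fwhm`, `similarity`, `effective_fwhm`, `boundary`
#'   (logical).
#' @export
smoothing_profile <- function(X, Xhat, mesh, fwhm_grid = 1:10, mask = NULL,
                              geo = NULL) {
  if (!length(fwhm_grid) || is.unsorted(fwhm_grid, strictly = TRUE))
    stop("smoothing_profile: fwhm_grid must be non-empty increasing",
         call. = FALSE)
  geo <- get_geodesics(mesh, geo)
  sim <- vapply(fwhm_grid, function(f) {
    Xs <- surface_smooth(X, mesh, f, geo = geo)
    fisher_mean(reconstruction_degree(Xs, Xhat, mask))
  }, numeric(1))
  i <- which.max(sim)
  list(fwhm = fwhm_grid, similarity = sim, effective_fwhm = fwhm_grid[i],
       boundary = i == 1L || i == length(fwhm_grid))
}

#' Covariate-adjusted (partial) correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' regression on the covariates (with intercept), with a two-sided p-value
#' from the t distribution on `n - 2 - n_covariates` degrees of freedom. With
#' no covariates this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector/matrix of covariates, or `NULL`.
#' @return list with `r`, `p`, `df`.
#' @export
adjusted_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  q <- if (is.null(covariates)) 0L else NCOL(covariates)
  if (n <= q + 2)
    stop_dim("adjusted_correlation: need n > covariates + 2 (n=%d, q=%d)", n, q)
  if (q > 0) {
    Cm <- cbind(1, covariates)
    if (qr(Cm)$rank < ncol(Cm))
      stop("adjusted_correlation: rank-deficient covariates", call. = FALSE)
    qrC <- qr(Cm)
    sx0 <- sd(x); sy0 <- sd(y)
    x <- qr.resid(qrC, x)
    y <- qr.resid(qrC, y)
    # a variable fully explained by the covariates has (numerically) zero
    # residual: perfect confound removal, partial r = 0
    if (sd(x) < 1e-10 * (sx0 + 1) || sd(y) < 1e-10 * (sy0 + 1))
      return(list(r = 0, p = 1, df = n - 2 - q))
  }
  r <- suppressWarnings(cor(x, y))
  if (is.na(r)) return(list(r = NA_real_, p = NA_real_, df = n - 2 - q))
  df <- n - 2 - q
  tt <- r * sqrt(df / max(1 - r^2, 1e-15))
  list(r = r, p = 2 * pt(-abs(tt), df), df = df)
}

#' Inter-session consistency of a subject-level score
#'
#' Quantifies whether subjects keep their rank across repeated scans: the
#' age-adjusted correlation between session scores (via
#' [adjusted_correlation()], controlling age at each scan) and the two-way
#' random-effects single-measure intraclass correlation ICC(2,1) on the
#' age-residualized scores.
#'
#' @param scores_s1,scores_s2 paired per-subject scores (equal length >= 3).
#' @param ages_s1,ages_s2 ages at each scan (used as covariates).
#' @return list with `partial_r`, `partial_p`, `icc`.
#' @export
intersession_consistency <- function(scores_s1, scores_s2, ages_s1, ages_s2) {
  n <- length(scores_s1)
  if (length(scores_s2) != n || length(ages_s1) != n || length(ages_s2) != n)
    stop("intersession_consistency: unpaired input lengths", call. = FALSE)
  if (n < 3) stop("intersession_consistency: need n >= 3 pairs", call. = FALSE)
  res1 <- qr.resid(qr(cbind(1, ages_s1)), scores_s1)
  res2 <- qr.resid(qr(cbind(1, ages_s2)), scores_s2)
  cov_m <- cbind(ages_s1, ages_s2)
  # equal (or collinear) session ages collapse to a single covariate
  if (qr(cbind(1, cov_m))$rank < 3) cov_m <- cov_m[, 1, drop = FALSE]
  pc <- adjusted_correlation(scores_s1, scores_s2, covariates = cov_m)
  list(partial_r = pc$r, partial_p = pc$p, icc = icc21(cbind(res1, res2)))
}

#' Two-way random-effects single-measure ICC(2,1)
#'
#' @param M n x k matrix (subjects x sessions).
#' @return scalar ICC.
#' @export
icc21 <- function(M) {
  n <- nrow(M); k <- ncol(M)
  mu <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  ss_rows <- k * sum((row_m - mu)^2)
  ss_cols <- n * sum((col_m - mu)^2)
  ss_err <- sum((M - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + mu)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
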