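#' Fit a linear latent basis
#'
#' Comparison bases for the VAE: `"spatial_ica"` fits a k-component spatial ICA
#' (PCA whitening to k dimensions followed by FastICA with deflation and tanh
#' contrast) on the concatenated training frames, columns scaled to unit norm;
#' `"parcellation"` builds the indicator/averaging matrix of supplied parcel
#' labels. The pseudoinverse is cached for encoding. Typical comparison ranks
#' are 50, 100, 200, 300 and 256.
#'
#' @param ts_list list of `cortical_ts` (or a single V x T matrix) used as
#'   training frames.
#' @param method `"spatial_ica"` or `"parcellation"`.
#' @param k number of components (ignored for parcellation).
#' @param seed RNG seed for ICA initialization.
#' @param labels integer parcel label per vertex (parcellation only; 0/NA =
#'   unassigned).
#' @return an object of class `linear_basis` with fields `A` (V x k), `pinv`
#'   (k x V), `method`, `k`, `seed`.
#' @export
fit_linear_basis <- function(ts_list, method = c("spatial_ica", "parcellation"),
                             k = 256L, seed = 1L, labels = NULL) {
  method <- match.arg(method)
  X <- if (is.matrix(ts_list)) ts_list
       else do.call(cbind, lapply(ts_list, function(t) t$values))
  if (method == "spatial_ica") {
    if (ncol(X) < k)
      stop_dim("fit_linear_basis: %d frames < k = %d", ncol(X), k)
    A <- with_seed(seed, {
      # spatial ICA: time points are the mixed variables, vertices the samples
      wh <- pca_whiten(t(X), k)
      W <- fastica_deflation(wh$Z)
      t(W %*% wh$Z)                   # V x k spatial maps
    })
    A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  } else {
    if (is.null(labels)) stop("parcellation needs per-vertex labels", call. = FALSE)
    lev <- sort(unique(labels[!is.na(labels) & labels > 0]))
    A <- vapply(lev, function(l) as.numeric(labels %in% l),
                numeric(length(labels)))
    k <- length(lev)
  }
  if (any(colSums(abs(A)) == 0))
    stop("fit_linear_basis: zero column in basis", call. = FALSE)
  structure(list(A = A, pinv = pinv(A), method = method, k = k,
                 seed = as.integer(seed)),
            class = "linear_basis")
}

## Moore-Penrose pseudoinverse via SVD
pinv <- function(A, tol = NULL) {
  sv <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

#' Encode frames with a linear basis
#'
#' `Y = A^+ X`: least-squares projection of each frame onto the basis columns.
#'
#' @param X V x T matrix (or `cortical_ts`).
#' @param basis a `linear_basis`.
#' @return k x T matrix of component timecourses.
#' @export
linear_encode <- function(X, basis) {
  if (inherits(X, "cortical_ts")) X <- X$values
  if (nrow(X) != nrow(basis$A))
    stop_dim("linear_encode: X has %d rows, basis has %d", nrow(X), nrow(basis$A))
  basis$pinv %*% X
}

#' Reconstruct frames from linear components
#'
#' `X~ = A Y`; composing with [linear_encode()] gives the orthogonal projection
#' of the data onto the basis column space.
#'
#' @param Y k x T component timecourses.
#' @param basis a `linear_basis`.
#' @return V x T reconstructed matrix.
#' @export
linear_reconstruct <- function(Y, basis) {
  if (nrow(Y) != ncol(basis$A))
    stop_dim("linear_reconstruct: Y has %d rows, basis has %d columns",
             nrow(Y), ncol(basis$A))
  basis$A %*% Y
}
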