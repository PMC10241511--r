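#' Per-subject component timecourse variances
#'
#' Applies the group unmixing to one subject's latent timeseries and returns
#' the sample variance of each independent component's timecourse.
#'
#' @param Z a `latent_ts` (or L x T matrix).
#' @param W unmixing matrix (components x L), e.g.
#'   `temporal_ica(...)$unmixing`.
#' @return numeric vector of per-component variances.
#' @export
ic_variance <- function(Z, W) {
  M <- if (inherits(Z, "latent_ts")) Z$mu else as.matrix(Z)
  if (ncol(M) < 3) stop("ic_variance: need T >= 3", call. = FALSE)
  if (ncol(W) != nrow(M))
    stop_dim("ic_variance: unmixing expects %d latents, got %d",
             ncol(W), nrow(M))
  apply(W %*% M, 1, var)
}

#' Age correlation of component variances
#'
#' Correlates each component's timecourse variance with age across subjects
#' and flags components significant under Benjamini-Hochberg FDR at `alpha`.
#' Zero-variance columns are excluded with a warning.
#'
#' @param variances subjects x components matrix (rows = subjects).
#' @param ages subject ages (n >= 4, non-constant).
#' @param alpha FDR level (default 0.05).
#' @return list with `r`, `p`, `p_adj`, `significant` (logical), `alpha`.
#' @export
variance_age_correlation <- function(variances, ages, alpha = 0.05) {
  n <- nrow(variances)
  if (n < 4) stop("variance_age_correlation: need n >= 4", call. = FALSE)
  if (sd(ages) < 1e-12)
    stop("variance_age_correlation: constant ages", call. = FALSE)
  sds <- apply(variances, 2, sd)
  zv <- sds < 1e-12
  if (any(zv))
    warning(sprintf("variance_age_correlation: %d zero-variance component(s) excluded",
                    sum(zv)), call. = FALSE)
  r <- rep(NA_real_, ncol(variances))
  r[!zv] <- suppressWarnings(as.vector(cor(variances[, !zv, drop = FALSE], ages)))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * pt(-abs(tt), n - 2)
  p_adj <- p.adjust(p, "BH")
  list(r = r, p = p, p_adj = p_adj,
       significant = !is.na(p_adj) & p_adj < alpha, alpha = alpha)
}

#' Split a cohort into young / median / old age groups
#'
#' Young: age <= `low`; old: age >= `high`; median: the remainder. The
#' defaults (39 and 43 postmenstrual weeks) bracket the term-age peak of a
#' neonatal cohort. Empty young or old groups raise a warning.
#'
#' @param ages subject ages (weeks).
#' @param low,high thresholds in weeks (`low < high`).
#' @return object of class `group_split` with index vectors `young`,
#'   `median`, `old` and the thresholds.
#' @export
split_age_groups <- function(ages, low = 39, high = 43) {
  if (!(low < high)) stop("split_age_groups: need low < high", call. = FALSE)
  young <- which(ages <= low)
  old <- which(ages >= high)
  med <- which(ages > low & ages < high)
  if (!length(young) || !length(old))
    warning("split_age_groups: empty young or old group", call. = FALSE)
  structure(list(young = young, median = med, old = old,
                 thresholds = c(low = low, high = high)),
            class = "group_split")
}

#' @exportS3Method base::print
print.group_split <- function(x, ...) {
  cat(sprintf("<group_split> young (<=%g wk): n=%d | median: n=%d | old (>=%g wk): n=%d\n",
              x$thresholds["low"], length(x$young), length(x$median),
              x$thresholds["high"], length(x$old)))
  invisible(x)
}

## stage-1 dual regression: per-subject spatial weights in latent space.
## Regress the subject's latent series (L x T) on the subject's component
## timecourses (k x T): B = Z C' (C C')^-1, L x k.
dual_regression_weights <- function(Z, W) {
  M <- if (inherits(Z, "latent_ts")) Z$mu else as.matrix(Z)
  C <- W %*% M                       # subject component timecourses
  Ct <- t(C)
  t(qr.coef(qr(Ct), t(M)))           # L x k
}

#' Group-level network map by dual regression
#'
#' Stage 1 regresses each subject's latent timeseries on that subject's
#' component timecourses (ordinary least squares), giving per-subject spatial
#' weights in latent space. Stage 2 averages the chosen component's weight
#' vector across the group and projects it to the cortex through the decoder
#' ([basis_to_cortex()]).
#'
#' @param latents non-empty list of `latent_ts` for the group.
#' @param W group unmixing matrix (components x L).
#' @param component component index.
#' @param model `vae_model` (decoder).
#' @param mapping `grid_mapping`.
#' @param n_vertices mesh vertex count.
#' @param n_scales,seed passed to [basis_to_cortex()].
#' @return a `cortical_map` (sign not yet fixed); the group latent basis is
#'   attached as attribute `"basis"`.
#' @export
group_network_map <- function(latents, W, component, model, mapping,
                              n_vertices, n_scales = 1000L, seed = 1L) {
  if (!length(latents)) stop("group_network_map: empty group", call. = FALSE)
  Bs <- lapply(latents, dual_regression_weights, W = W)
  basis <- rowMeans(vapply(Bs, function(B) B[, component], numeric(nrow(Bs[[1]]))))
  map <- basis_to_cortex(basis, model, mapping, n_vertices,
                         n_scales = n_scales, seed = seed)
  attr(map, "basis") <- basis
  map
}

#' Latent-space group difference map
#'
#' Subtracts the group bases in latent space and projects the difference
#' through the decoder; with a shared Monte-Carlo seed the map is
#' antisymmetric in its arguments up to Monte-Carlo error.
#'
#' @param basisA,basisB latent basis vectors (equal length), e.g. the
#'   `"basis"` attributes of [group_network_map()] outputs.
#' @param model `vae_model`.
#' @param mapping `grid_mapping`.
#' @param n_vertices mesh vertex count.
#' @param n_scales,seed passed to [basis_to_cortex()].
#' @return a `cortical_map` of the difference (A minus B).
#' @export
latent_difference_map <- function(basisA, basisB, model, mapping, n_vertices,
                                  n_scales = 1000L, seed = 1L) {
  if (length(basisA) != length(basisB))
    stop_dim("latent_difference_map: basis lengths differ (%d vs %d)",
             length(basisA), length(basisB))
  basis_to_cortex(basisA - basisB, model, mapping, n_vertices,
                  n_scales = n_scales, seed = seed)
}
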