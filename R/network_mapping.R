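#' Concatenate latent timeseries across subjects
#'
#' Column-wise concatenation preserving subject order, with the boundary
#' indices recorded (boundaries[i]..boundaries[i+1] spans subject i's columns,
#' 0-offset convention: `boundaries = c(0, cumsum(T_i))`).
#'
#' @param latents non-empty list of `latent_ts` (equal latent dimension).
#' @return list with `Z` (L x sum(T)), `boundaries`, `subject_id`.
#' @export
concat_latents <- function(latents) {
  if (!length(latents)) stop("concat_latents: empty list", call. = FALSE)
  Ls <- vapply(latents, function(z) nrow(z$mu), integer(1))
  if (length(unique(Ls)) != 1)
    stop_dim("concat_latents: latent dimensions differ (%s)",
             paste(unique(Ls), collapse = ", "))
  Ts <- vapply(latents, function(z) ncol(z$mu), integer(1))
  list(Z = do.call(cbind, lapply(latents, function(z) z$mu)),
       boundaries = c(0L, cumsum(Ts)),
       subject_id = vapply(latents, function(z) as.character(z$subject_id),
                           character(1)))
}

#' Temporal ICA over concatenated latent timeseries
#'
#' Reduces the latent timecourses to `n_components` principal components and
#' unmixes them with extended Infomax ICA, yielding temporally independent
#' component timecourses. Components are ordered by explained variance; each
#' is defined up to sign. The default component count is 30.
#'
#' @param Zcat L x T matrix (e.g. `concat_latents(...)$Z`) or the list output
#'   of [concat_latents()].
#' @param n_components number of independent components (default 30).
#' @param seed RNG seed for the ICA initialization.
#' @return object of class `network_basis` with `unmixing` (n_components x L:
#'   latent series -> component series), `mixing` (L x n_components: component
#'   -> latent basis vectors), `timecourses` (n_components x T), `order`
#'   (variance ranks), `seed`.
#' @export
temporal_ica <- function(Zcat, n_components = 30L, seed = 1L) {
  if (is.list(Zcat) && !is.matrix(Zcat)) Zcat <- Zcat$Z
  L <- nrow(Zcat); Tn <- ncol(Zcat)
  if (Tn <= n_components)
    stop_dim("temporal_ica: T = %d must exceed n_components = %d",
             Tn, n_components)
  with_seed(seed, {
    wh <- pca_whiten(Zcat, n_components)
    W <- infomax_ica(wh$Z)
    # unit-variance component convention (ICA scale indeterminacy)
    sds <- sqrt(apply(W %*% wh$Z, 1, var))
    W <- W / sds
    # order components by explained variance in latent space
    Wi <- solve(W)                           # whitened mixing
    M_lat <- wh$dewhiten %*% Wi              # L x k
    ord <- order(colSums(M_lat^2), decreasing = TRUE)
    W <- W[ord, , drop = FALSE]
    # full-rank unmixing latent -> components, and mixing components -> latent
    unmix <- W %*% wh$K                      # k x L
    mixing <- wh$dewhiten %*% solve(W)       # L x k; unmix %*% mixing = I
    # fix component signs: positive skewness of the timecourse
    tc <- unmix %*% (Zcat - rowMeans(Zcat))
    sk <- rowMeans(tc^3)
    fl <- ifelse(sk < 0, -1, 1)
    unmix <- unmix * fl
    mixing <- t(t(mixing) * fl)
    tc <- tc * fl
    structure(list(unmixing = unmix, mixing = mixing, timecourses = tc,
                   n_components = as.integer(n_components),
                   latent_dim = L, seed = as.integer(seed)),
              class = "network_basis")
  })
}

#' @exportS3Method base::print
print.network_basis <- function(x, ...) {
  cat(sprintf("<network_basis> %d components over %d latents (seed %d)\n",
              x$n_components, x$latent_dim, x$seed))
  invisible(x)
}

#' Project a latent basis to a cortical map through the decoder
#'
#' Monte-Carlo linearization of the (nonlinear) decoder around the basis
#' direction: draw `n_scales` standard-normal scaling factors s, decode each
#' `s * b`, and take per cortical vertex the sample covariance between s and
#' the decoded activity. For a linear decoder D this is exactly proportional
#' to `D b`.
#'
#' @param basis_vector latent basis (length `n_latent`).
#' @param model the `vae_model` whose decoder is used, or a function
#'   `z -> V x n matrix` mapping a latent matrix (L x n) straight to cortical
#'   values (used for analytic oracles).
#' @param mapping `grid_mapping` for the inverse reformatting (ignored when
#'   `model` is a function).
#' @param n_vertices total mesh vertex count.
#' @param n_scales Monte-Carlo draws (default 1000).
#' @param seed RNG seed (map is deterministic given the seed).
#' @return object of class `cortical_map`: `values` per vertex, `sign_fixed`,
#'   `threshold_fraction` fields.
#' @export
basis_to_cortex <- function(basis_vector, model, mapping = NULL,
                            n_vertices = NULL, n_scales = 1000L, seed = 1L) {
  if (inherits(model, "vae_model") &&
      length(basis_vector) != model$config$n_latent)
    stop_dim("basis_to_cortex: basis length %d != n_latent %d",
             length(basis_vector), model$config$n_latent)
  with_seed(seed, {
    s <- rnorm(n_scales)
    # accumulate the per-vertex cross-products in blocks so memory stays
    # bounded for large Monte-Carlo sizes
    block <- 2048L
    sum_x <- NULL; sum_xs <- NULL
    for (start in seq(1, n_scales, by = block)) {
      idx <- start:min(start + block - 1, n_scales)
      Zs <- outer(basis_vector, s[idx])      # L x block
      X <- if (is.function(model)) model(Zs)
           else from_grid(decode(model, Zs), mapping, n_vertices)
      if (is.null(sum_x)) { sum_x <- numeric(nrow(X)); sum_xs <- numeric(nrow(X)) }
      sum_x <- sum_x + rowSums(X)
      sum_xs <- sum_xs + as.vector(X %*% s[idx])
    }
    vals <- (sum_xs - sum_x * mean(s)) / (n_scales - 1)
    cortical_map(vals)
  })
}

#' Cortical map container
#'
#' @param values per-vertex values.
#' @param sign_fixed has [fix_sign()] been applied.
#' @param threshold_fraction threshold applied by [threshold_map()] (0 = none).
#' @return object of class `cortical_map`.
#' @export
cortical_map <- function(values, sign_fixed = FALSE, threshold_fraction = 0) {
  structure(list(values = as.numeric(values), sign_fixed = sign_fixed,
                 threshold_fraction = threshold_fraction),
            class = "cortical_map")
}

#' Fix the sign of a cortical map
#'
#' Negates the whole map iff the vertex with the strongest absolute value is
#' negative, so the strongest region is always in the activation (+) state.
#' Ties go to the lower vertex index. An all-zero map is returned unchanged
#' with a warning.
#'
#' @param map a `cortical_map` (or numeric vector).
#' @return sign-fixed `cortical_map`.
#' @export
fix_sign <- function(map) {
  v <- if (inherits(map, "cortical_map")) map$values else as.numeric(map)
  if (all(v == 0)) {
    warning("fix_sign: all-zero map", call. = FALSE)
    return(cortical_map(v, sign_fixed = TRUE,
                        threshold_fraction =
                          if (inherits(map, "cortical_map")) map$threshold_fraction else 0))
  }
  peak <- which.max(abs(v))[1]   # ties -> lowest index
  if (v[peak] < 0) v <- -v
  cortical_map(v, sign_fixed = TRUE,
               threshold_fraction =
                 if (inherits(map, "cortical_map")) map$threshold_fraction else 0)
}

#' Threshold a cortical map
#'
#' Sets values with `|v| < fraction * max|v|` to zero (default fraction 0.15).
#'
#' @param map a `cortical_map` (or numeric vector).
#' @param fraction threshold fraction in `[0, 1]`.
#' @return thresholded `cortical_map`.
#' @export
threshold_map <- function(map, fraction = 0.15) {
  stopifnot(fraction >= 0, fraction <= 1)
  v <- if (inherits(map, "cortical_map")) map$values else as.numeric(map)
  cut <- fraction * max(abs(v))
  v[abs(v) < cut] <- 0
  cortical_map(v, sign_fixed = if (inherits(map, "cortical_map")) map$sign_fixed else FALSE,
               threshold_fraction = fraction)
}

#' One-to-one pairing of two component sets
#'
#' Pairs components across groups by absolute Pearson correlation: greedy by
#' default (repeatedly take the highest remaining |r|, each component used
#' once), or the globally optimal assignment (exhaustive, k <= 8) with
#' `method = "optimal"`.
#'
#' @param basesA,basesB k x d matrices (rows = component vectors; equal k).
#' @param method `"greedy"` or `"optimal"`.
#' @return data.frame with `a`, `b`, `abs_r`, sorted by decreasing |r|.
#' @export
match_bases <- function(basesA, basesB, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  basesA <- as.matrix(basesA); basesB <- as.matrix(basesB)
  if (nrow(basesA) != nrow(basesB))
    stop_dim("match_bases: component counts differ (%d vs %d)",
             nrow(basesA), nrow(basesB))
  k <- nrow(basesA)
  R <- abs(suppressWarnings(cor(t(basesA), t(basesB))))
  R[is.na(R)] <- 0
  if (method == "greedy") {
    pair_a <- integer(k); pair_b <- integer(k); rr <- numeric(k)
    Rw <- R
    for (i in seq_len(k)) {
      ij <- arrayInd(which.max(Rw), dim(Rw))
      pair_a[i] <- ij[1]; pair_b[i] <- ij[2]; rr[i] <- Rw[ij]
      Rw[ij[1], ] <- -1; Rw[, ij[2]] <- -1
    }
  } else {
    if (k > 8) stop("match_bases: optimal assignment limited to k <= 8",
                    call. = FALSE)
    perms <- all_perms(k)
    scores <- vapply(perms, function(p) sum(R[cbind(seq_len(k), p)]), numeric(1))
    p <- perms[[which.max(scores)]]
    pair_a <- seq_len(k); pair_b <- p; rr <- R[cbind(pair_a, pair_b)]
    ord <- order(rr, decreasing = TRUE)
    pair_a <- pair_a[ord]; pair_b <- pair_b[ord]; rr <- rr[ord]
  }
  data.frame(a = pair_a, b = pair_b, abs_r = rr)
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) for (pos in 0:(k - 1L))
    out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}

#' Reproducibility of network bases across groups
#'
#' For each of `n_seeds` ICA initializations, runs [temporal_ica()] per group,
#' pairs the bases of every group pair with [match_bases()], and averages the
#' matched |r| over the top-k pairs for each k in `top_k`. Returns mean and sd
#' across seeds per group pair and k.
#'
#' @param groups named list (>= 2) of L x T concatenated latent matrices.
#' @param n_components components per ICA (default 30).
#' @param n_seeds ICA initializations (default 100).
#' @param top_k numbers of best-matched pairs to average (default
#'   `c(1, 3, 5, 10, 15)`).
#' @param seed base RNG seed.
#' @return data.frame with `pair`, `k`, `mean_abs_r`, `sd_abs_r`.
#' @export
reproducibility_curve <- function(groups, n_components = 30L, n_seeds = 100L,
                                  top_k = c(1, 3, 5, 10, 15), seed = 1L) {
  if (length(groups) < 2) stop("reproducibility_curve: need >= 2 groups",
                               call. = FALSE)
  top_k <- top_k[top_k <= n_components]
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  pairs <- utils::combn(length(groups), 2)
  acc <- array(NA_real_, c(ncol(pairs), length(top_k), n_seeds))
  for (s in seq_len(n_seeds)) {
    bases <- lapply(groups, function(Z)
      temporal_ica(Z, n_components, seed = seed + s)$mixing)
    for (pi in seq_len(ncol(pairs))) {
      m <- match_bases(t(bases[[pairs[1, pi]]]), t(bases[[pairs[2, pi]]]))
      for (ki in seq_along(top_k))
        acc[pi, ki, s] <- mean(m$abs_r[seq_len(top_k[ki])])
    }
  }
  out <- expand.grid(pair = apply(pairs, 2, function(p)
    paste(nm[p[1]], nm[p[2]], sep = " vs ")), k = top_k,
    stringsAsFactors = FALSE)
  out$mean_abs_r <- as.vector(apply(acc, c(1, 2), mean))
  out$sd_abs_r <- as.vector(apply(acc, c(1, 2), sd))
  out
}
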