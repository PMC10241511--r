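#' Synthetic two-hemisphere cortical mesh
#'
#' Builds an icosphere per hemisphere (recursive subdivision of an icosahedron
#' projected back to the sphere), with the right hemisphere a mirrored copy of
#' the left. Vertex counts follow the icosphere recurrence `V = 10 * 4^s + 2`,
#' faces `F = 20 * 4^s`. Hemisphere centres are offset along x so the meshes do
#' not intersect; the 5% of vertices nearest each hemisphere's inner (medial)
#' pole are flagged as the medial wall and excluded from analysis masks.
#'
#' @param subdivisions number of subdivision steps (>= 0).
#' @param radius_mm sphere radius in mm (default 60, about a neonatal
#'   hemisphere's bounding radius).
#' @return an object of class `cortical_mesh` with fields `vertices` (N x 3,
#'   mm), `triangles` (M x 3, 1-based), `hemisphere` (factor `L`/`R`),
#'   `medial_mask` (logical, `TRUE` = medial wall), `mesh_id`.
#' @export
make_mesh <- function(subdivisions = 3L, radius_mm = 60) {
  stopifnot(subdivisions >= 0, radius_mm > 0)
  ico <- icosphere(subdivisions)
  nv <- nrow(ico$vertices)
  offset <- radius_mm * 1.1
  vl <- ico$vertices * radius_mm
  vl[, 1] <- vl[, 1] - offset
  vr <- ico$vertices * radius_mm
  vr[, 1] <- -vr[, 1] + offset           # mirror in x
  tri_r <- ico$triangles[, c(1, 3, 2)] + nv  # flip winding to keep orientation
  vertices <- rbind(vl, vr)
  hemisphere <- factor(rep(c("L", "R"), each = nv), levels = c("L", "R"))
  # medial wall: vertices nearest the inner pole (facing the other hemisphere)
  inner_l <- c(0, 0, 0); inner_l[1] <- -offset + radius_mm  # +x pole of left sphere
  inner_r <- c(0, 0, 0); inner_r[1] <- offset - radius_mm   # -x pole of right sphere
  d_l <- sqrt(colSums((t(vl) - inner_l)^2))
  d_r <- sqrt(colSums((t(vr) - inner_r)^2))
  k <- max(1L, ceiling(0.05 * nv))
  medial <- logical(2 * nv)
  medial[order(d_l)[seq_len(k)]] <- TRUE
  medial[nv + order(d_r)[seq_len(k)]] <- TRUE
  structure(list(vertices = vertices,
                 triangles = rbind(ico$triangles, tri_r),
                 hemisphere = hemisphere, medial_mask = medial,
                 radius_mm = radius_mm, subdivisions = subdivisions,
                 mesh_id = sprintf("icosphere-s%d-r%g", subdivisions, radius_mm)),
            class = "cortical_mesh")
}

#' @exportS3Method base::print
print.cortical_mesh <- function(x, ...) {
  cat(sprintf("<cortical_mesh> %s  V=%d (%d/hemisphere)  F=%d  medial=%d\n",
              x$mesh_id, nrow(x$vertices), nrow(x$vertices) / 2,
              nrow(x$triangles), sum(x$medial_mask)))
  invisible(x)
}

icosphere <- function(subdivisions) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    edges <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
    ek <- edge_key(edges[, 1], edges[, 2])
    dup <- duplicated(ek)
    edges <- edges[!dup, , drop = FALSE]; ek <- ek[!dup]
    mid <- (v[edges[, 1], ] + v[edges[, 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    mid_idx <- stats::setNames(nrow(v) + seq_len(nrow(mid)), ek)
    v <- rbind(v, mid)
    m12 <- mid_idx[edge_key(f[, 1], f[, 2])]
    m23 <- mid_idx[edge_key(f[, 2], f[, 3])]
    m31 <- mid_idx[edge_key(f[, 3], f[, 1])]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
    dimnames(f) <- NULL
  }
  list(vertices = v, triangles = f)
}

## edge list (two columns, undirected, unique) of a mesh
mesh_edges <- function(mesh) {
  f <- mesh$triangles
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

## geodesic distances approximated by edge-graph shortest paths, per hemisphere
## (hemispheres are disconnected); entries across hemispheres are Inf.
mesh_geodesics <- function(mesh) {
  e <- mesh_edges(mesh)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], ] - mesh$vertices[e[, 2], ])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::E(g)$weight <- w
  igraph::distances(g)
}

## cache geodesics on the mesh object's environment-free list: recompute cheap
## for desk-scale meshes, but allow callers to pass a precomputed matrix.
get_geodesics <- function(mesh, geo = NULL) {
  if (!is.null(geo)) return(geo)
  mesh_geodesics(mesh)
}

#' Ground-truth generator manifest
#'
#' Describes the generative model of the synthetic cohort: `K` smooth spatial
#' network maps (rows unit-norm), a baseline source covariance, a per-pair
#' slope of covariance versus age (`age_effect`, weeks^-1), noise scales and
#' the age range. By default the sources are independent and age acts on the
#' source variances only (diagonal `age_effect`), which makes the sources
#' recoverable by temporal ICA and drives both latent-FC age prediction and the
#' component-variance-versus-age analysis.
#'
#' @param network_maps K x V matrix of unit-norm spatial maps (see
#'   [make_networks()]).
#' @param base_cov K x K baseline source covariance (default identity).
#' @param age_effect K x K symmetric slope matrix; default
#'   `diag(c(0.05, -0.03, 0.07, 0, 0.02, 0, ...))` truncated/recycled to K.
#' @param noise_sd thermal (white) vertex noise sd (default 0.6).
#' @param structured_noise_sd spatially smooth noise sd (default 0.8).
#' @param structured_noise_fwhm_mm smoothness of the structured noise (25 mm;
#'   physiological BOLD noise is spatially broad, giving a smoothly decaying
#'   spatial noise eigen-spectrum).
#' @param signal_scale average per-vertex signal sd (default 1).
#' @param age_range age range in postmenstrual weeks (default the dHCP-like
#'   24.29-44.87).
#' @param ar_coef temporal AR(1) coefficient of the sources (0.3).
#' @param subject_noise_sd_log lognormal sd of the per-subject noise multiplier
#'   (0.15), giving subjects distinct SNR.
#' @param seed integer seed recorded in the manifest.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(network_maps, base_cov = NULL, age_effect = NULL,
                            noise_sd = 0.6, structured_noise_sd = 0.8,
                            structured_noise_fwhm_mm = 25, signal_scale = 1,
                            age_range = c(24.29, 44.87), ar_coef = 0.3,
                            subject_noise_sd_log = 0.15, seed = 1L) {
  K <- nrow(network_maps)
  rn <- sqrt(rowSums(network_maps^2))
  if (any(abs(rn - 1) > 1e-6))
    network_maps <- network_maps / rn
  if (is.null(base_cov)) base_cov <- diag(K)
  if (is.null(age_effect)) {
    g <- rep_len(c(0.05, -0.03, 0.07, 0, 0.02), K)
    age_effect <- diag(g, K)
  }
  stopifnot(all(dim(base_cov) == K), all(dim(age_effect) == K))
  if (max(abs(base_cov - t(base_cov))) > 1e-10 ||
      max(abs(age_effect - t(age_effect))) > 1e-10)
    stop("synthetic_truth: base_cov and age_effect must be symmetric",
         call. = FALSE)
  age0 <- mean(age_range)
  for (a in age_range) {
    ev <- min(eigen(base_cov + (a - age0) * age_effect, symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev < -1e-8)
      stop_dim("synthetic_truth: covariance not PSD at age %.4g wk", a)
  }
  structure(list(network_maps = network_maps, base_cov = base_cov,
                 age_effect = age_effect, age0 = age0, noise_sd = noise_sd,
                 structured_noise_sd = structured_noise_sd,
                 structured_noise_fwhm_mm = structured_noise_fwhm_mm,
                 signal_scale = signal_scale, age_range = age_range,
                 ar_coef = ar_coef, subject_noise_sd_log = subject_noise_sd_log,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Smooth ground-truth network maps
#'
#' Draws `K` Gaussian random fields on the mesh, smooths them geodesically
#' (kernel FWHM `smoothness_mm`), orthonormalizes (QR) so the maps are mutually
#' orthogonal and unit-norm, and zeroes the medial wall.
#'
#' @param mesh a `cortical_mesh`.
#' @param K number of networks (1 <= K <= V).
#' @param smoothness_mm spatial smoothing FWHM in mm (default 15).
#' @param seed RNG seed.
#' @param geo optional precomputed geodesic matrix (see details in
#'   [surface_smooth()]).
#' @return K x V matrix of unit-norm maps.
#' @export
make_networks <- function(mesh, K, smoothness_mm = 15, seed = 1L, geo = NULL) {
  V <- nrow(mesh$vertices)
  if (K < 1 || K > V) stop_dim("make_networks: need 1 <= K (%d) <= V (%d)", K, V)
  with_seed(seed, {
    X <- matrix(rnorm(V * K), V, K)
    if (smoothness_mm > 0) {
      ts <- cortical_ts(X, mesh_id = mesh$mesh_id)
      X <- surface_smooth(ts, mesh, smoothness_mm, geo = geo)$values
    }
    X[mesh$medial_mask, ] <- 0
    Q <- qr.Q(qr(X))
    t(Q)  # rows orthonormal, hence unit-norm
  })
}

## AR(1) series (K x T) with stationary covariance Sigma and Laplace innovations
ar1_sources <- function(Sigma, Tn, ar_coef) {
  K <- nrow(Sigma)
  L <- chol_psd(Sigma)
  # Laplace innovations with unit variance: rexp difference / sqrt(2) * sqrt2...
  rlap <- function(n) {
    u <- runif(n) - 0.5
    -sign(u) * log(1 - 2 * abs(u)) / sqrt(2)  # unit-variance Laplace
  }
  Y <- matrix(0, K, Tn)
  Y[, 1] <- L %*% rlap(K)
  s <- sqrt(1 - ar_coef^2)
  for (t in 2:Tn) Y[, t] <- ar_coef * Y[, t - 1] + s * (L %*% rlap(K))
  Y
}

chol_psd <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

#' Cohort presets
#'
#' Two acquisition profiles mimicking the real cohorts' frame counts, sampling
#' intervals and noise levels, plus a desk-scale profile for simulation
#' studies.
#'
#' @param profile `"dhcp_like"` (T=1400, TR=0.392 s), `"dbi_like"` (T=150,
#'   TR=2 s, doubled thermal noise) or `"desk"` (T=150, TR=0.72 s).
#' @return a list of simulate_cohort arguments.
#' @export
cohort_profile <- function(profile = c("dhcp_like", "dbi_like", "desk")) {
  switch(match.arg(profile),
         dhcp_like = list(T = 1400L, tr_seconds = 0.392, noise_mult = 1,
                          dataset_tag = "dHCP-like"),
         dbi_like = list(T = 150L, tr_seconds = 2, noise_mult = 2,
                         dataset_tag = "DBI-like"),
         desk = list(T = 150L, tr_seconds = 0.72, noise_mult = 1,
                     dataset_tag = "synthetic"))
}

#' Simulate a cohort of surface fMRI scans with known truth
#'
#' Per subject: an age is drawn uniformly in `truth$age_range`; source
#' timecourses are AR(1) with unit-variance Laplace innovations and stationary
#' covariance `base_cov + (age - age0) * age_effect`; they are projected
#' through the network maps (scaled so the mean per-vertex signal sd is
#' `signal_scale`), spatially structured noise plus white thermal noise is
#' added, and rows are standardized. All draws are reproducible from
#' `(seed, truth)` and recorded in the returned manifest.
#'
#' @param mesh a `cortical_mesh`.
#' @param truth a [synthetic_truth()].
#' @param n_subjects number of subjects.
#' @param T frames per scan.
#' @param tr_seconds sampling interval.
#' @param seed RNG seed.
#' @param noise_mult multiplier on both noise sds (profile dependent).
#' @param dataset_tag label stored in each scan.
#' @param session_id session label (default "ses-01").
#' @param ages optional explicit ages (length `n_subjects`), overriding the
#'   uniform draw.
#' @param geo optional precomputed geodesic matrix, reused for the structured
#'   noise smoothing.
#' @return list with `scans` (list of `cortical_ts`), `table` (a
#'   [subject_table()]), `manifest` (ages, per-subject noise multipliers,
#'   source covariances, seed).
#' @export
simulate_cohort <- function(mesh, truth, n_subjects, T = 150L,
                            tr_seconds = 0.72, seed = 1L, noise_mult = 1,
                            dataset_tag = "synthetic", session_id = "ses-01",
                            ages = NULL, geo = NULL) {
  stopifnot(inherits(mesh, "cortical_mesh"), inherits(truth, "synthetic_truth"))
  M <- truth$network_maps
  K <- nrow(M); V <- ncol(M)
  if (V != nrow(mesh$vertices))
    stop_dim("simulate_cohort: truth maps have V=%d, mesh has V=%d",
             V, nrow(mesh$vertices))
  # scale so that mean per-vertex signal variance is signal_scale^2 when the
  # source variances are 1: mean_v sum_k M[k,v]^2 = K/V for unit-norm rows.
  proj <- t(M) * truth$signal_scale * sqrt(V / K)
  smooth_w <- NULL
  if (truth$structured_noise_sd > 0) {
    geo <- get_geodesics(mesh, geo)
    smooth_w <- smoothing_weights(geo, truth$structured_noise_fwhm_mm)
  }
  with_seed(seed, {
    age_vec <- if (is.null(ages))
      runif(n_subjects, truth$age_range[1], truth$age_range[2]) else ages
    noise_mult_subj <- exp(rnorm(n_subjects, 0, truth$subject_noise_sd_log))
    scans <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      Sigma <- truth$base_cov + (age_vec[i] - truth$age0) * truth$age_effect
      ev <- min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-8)
        stop_dim("simulate_cohort: covariance not PSD at age %.4g wk", age_vec[i])
      Y <- ar1_sources(Sigma, T, truth$ar_coef)
      X <- proj %*% Y
      nm <- noise_mult * noise_mult_subj[i]
      if (!is.null(smooth_w)) {
        N1 <- matrix(rnorm(V * T), V, T)
        N1 <- as.matrix(smooth_w %*% N1)
        # renormalize smoothed noise back to unit sd before scaling
        N1 <- N1 / sqrt(mean(N1^2))
        X <- X + truth$structured_noise_sd * nm * N1
      }
      if (truth$noise_sd > 0)
        X <- X + matrix(rnorm(V * T, sd = truth$noise_sd * nm), V, T)
      fd <- abs(rnorm(T, 0.15, 0.08)) + 0.02
      ts <- cortical_ts(X, mesh_id = mesh$mesh_id,
                        subject_id = sprintf("sub-%03d", i),
                        session_id = session_id, age_weeks = age_vec[i],
                        dataset_tag = dataset_tag, tr_seconds = tr_seconds,
                        fd_series = fd)
      scans[[i]] <- normalize_timeseries(ts)
    }
    tab <- subject_table(sprintf("sub-%03d", seq_len(n_subjects)),
                         rep(session_id, n_subjects), age_vec,
                         dataset_tag = dataset_tag,
                         mean_fd = vapply(scans, function(s) mean(s$fd_series),
                                          numeric(1)))
    list(scans = scans, table = tab,
         manifest = list(ages = age_vec, noise_mult_subj = noise_mult_subj,
                         seed = as.integer(seed), T = T,
                         tr_seconds = tr_seconds, noise_mult = noise_mult,
                         truth_seed = truth$seed))
  })
}
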