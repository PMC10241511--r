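test_that("reconstruction degree matches the Pearson formula and handles edge cases", {
  X <- matrix(c(1, 2, 3, 4), 4, 1)
  expect_equal(reconstruction_degree(X, X)[1], 1)
  expect_equal(reconstruction_degree(X, -X)[1], -1)
  Xh <- matrix(c(1, 2, 3, 5), 4, 1)
  expect_equal(reconstruction_degree(X, Xh)[1], 0.9827, tolerance = 1e-4)
  # constant frame -> NA with warning
  Xc <- cbind(X, rep(2, 4)); Xhc <- cbind(Xh, rnorm(4))
  expect_warning(r <- reconstruction_degree(Xc, Xhc), "constant")
  expect_true(is.na(r[2]) && !is.na(r[1]))
  expect_error(reconstruction_degree(X, Xh[1:3, , drop = FALSE]), "mismatch")
})

test_that("fisher_mean averages on the z scale", {
  expect_equal(fisher_mean(c(0, 0, 0)), 0)
  expect_equal(fisher_mean(rep(0.5, 4)), 0.5)
  expect_equal(fisher_mean(c(0.2, 0.8)), tanh(mean(atanh(c(0.2, 0.8)))))
  expect_equal(fisher_mean(c(0.2, 0.8)), 0.5721, tolerance = 1e-4)
  expect_equal(fisher_mean(c(0.3, NA)), 0.3)       # missing skipped
  expect_error(fisher_mean(c(NA, NA)), "missing")
  # bounded by the extremes and monotone
  set.seed(8)
  r <- runif(20, -0.5, 0.9)
  expect_gt(fisher_mean(r), min(r)); expect_lt(fisher_mean(r), max(r))
  expect_gt(fisher_mean(r + 0.05), fisher_mean(r))
  expect_equal(fisher_mean(c(1, 1)), 1, tolerance = 1e-6)  # clipping
})

test_that("surface smoothing preserves constants, respects fwhm=0 and has the right scale", {
  mesh <- fx_mesh3(); geo <- fx_geo3()
  V <- nrow(mesh$vertices)
  set.seed(9)
  X <- matrix(rnorm(V * 2), V, 2)
  expect_identical(surface_smooth(X, mesh, 0, geo = geo), X)
  const <- matrix(5, V, 1)
  expect_equal(surface_smooth(const, mesh, 8, geo = geo), const,
               tolerance = 1e-10)
  expect_error(surface_smooth(X, mesh, -1), ">= 0")
  # impulse response: half-maximum geodesic radius within 20% of fwhm/2
  # (finer subdivision-4 mesh so the kernel is resolved)
  mesh4 <- fx_mesh4()
  geo4 <- fx_geo4()
  v0 <- which(mesh4$hemisphere == "L" & !mesh4$medial_mask)[100]
  imp <- matrix(0, nrow(mesh4$vertices), 1); imp[v0] <- 1
  fwhm <- 12
  sm <- surface_smooth(imp, mesh4, fwhm, geo = geo4)[, 1]
  d <- geo4[v0, ]
  half <- sm[v0] / 2
  # interpolate the crossing radius on sorted distances
  ord <- order(d[is.finite(d)])
  dd <- d[is.finite(d)][ord]; vv <- sm[is.finite(d)][ord]
  below <- which(vv < half & dd > 0)[1]
  r_half <- approx(vv[c(below - 1, below)], dd[c(below - 1, below)], xout = half)$y
  expect_lt(abs(r_half - fwhm / 2) / (fwhm / 2), 0.2)
})

test_that("smoothing profile recovers a constructed smoothing level", {
  # the 1-10 mm grid needs the subdivision-4 mesh (edge ~4 mm) to resolve
  mesh <- fx_mesh4(); geo <- fx_geo4()
  set.seed(10)
  V <- nrow(mesh$vertices)
  X <- matrix(rnorm(V * 6), V, 6)
  msk <- !mesh$medial_mask
  Xs5 <- surface_smooth(X, mesh, 5, geo = geo)
  prof <- smoothing_profile(X, Xs5, mesh, fwhm_grid = 1:10, mask = msk, geo = geo)
  expect_equal(prof$effective_fwhm, 5)
  expect_false(prof$boundary)
  # identical reconstruction peaks at the smallest fwhm, flagged boundary
  prof0 <- smoothing_profile(X, X, mesh, fwhm_grid = 1:10, mask = msk, geo = geo)
  expect_equal(prof0$effective_fwhm, 1)
  expect_true(prof0$boundary)
  expect_error(smoothing_profile(X, X, mesh, fwhm_grid = c(3, 2)), "increasing")
})

test_that("more-smoothed reconstructions peak at strictly larger fwhm", {
  mesh <- fx_mesh4(); geo <- fx_geo4()
  set.seed(11)
  X <- matrix(rnorm(nrow(mesh$vertices) * 4), ncol = 4)
  msk <- !mesh$medial_mask
  p4 <- smoothing_profile(X, surface_smooth(X, mesh, 4, geo = geo), mesh,
                          1:10, msk, geo)
  p7 <- smoothing_profile(X, surface_smooth(X, mesh, 7, geo = geo), mesh,
                          1:10, msk, geo)
  expect_lt(p4$effective_fwhm, p7$effective_fwhm)
})

test_that("adjusted correlation removes covariate-driven association", {
  set.seed(12)
  # no covariates -> plain Pearson
  x <- rnorm(50); y <- x + rnorm(50)
  expect_equal(adjusted_correlation(x, y)$r, cor(x, y))
  # y equals the covariate -> partial r ~ 0
  z <- rnorm(200); y2 <- z
  x2 <- z + rnorm(200, 0, 0.5)
  out <- adjusted_correlation(x2, y2, z)
  expect_lt(abs(out$r), 1e-8)
  # shared covariate-driven component only: plain r large, partial r in null band
  n <- 500
  c0 <- rnorm(n)
  xa <- 2 * c0 + rnorm(n); ya <- -1.5 * c0 + rnorm(n)
  plain <- cor(xa, ya)
  part <- adjusted_correlation(xa, ya, c0)
  expect_gt(abs(plain), 0.4)
  expect_lt(abs(part$r), 2.58 / sqrt(n))   # 1% two-sided null band
  expect_error(adjusted_correlation(xa, ya, cbind(c0, c0)), "rank")
})

test_that("ICC(2,1) recovers designed variance shares", {
  # identical sessions -> ICC 1, partial r 1
  set.seed(13)
  s <- rnorm(40); ages <- runif(40, 30, 44)
  out <- intersession_consistency(s, s, ages, ages)
  expect_equal(out$icc, 1, tolerance = 1e-10)
  expect_equal(out$partial_r, 1, tolerance = 1e-10)
  # independent scores -> both within null bands (n = 1000)
  n <- 1000
  a1 <- runif(n, 30, 44); a2 <- a1 + runif(n, 2, 8)
  o0 <- intersession_consistency(rnorm(n), rnorm(n), a1, a2)
  expect_lt(abs(o0$partial_r), 2.58 / sqrt(n))
  expect_lt(abs(o0$icc), 0.09)
  # variance-component oracle: subject share 0.5 -> ICC = 0.5 +/- 0.07
  subj <- rnorm(n, 0, sqrt(0.5))
  s1 <- subj + rnorm(n, 0, sqrt(0.5))
  s2 <- subj + rnorm(n, 0, sqrt(0.5))
  o5 <- intersession_consistency(s1, s2, a1, a2)
  expect_equal(o5$icc, 0.5, tolerance = 0.07 / 0.5)
  expect_error(intersession_consistency(s1, s2[1:10], a1, a2), "unpaired")
})

test_that("trained-VAE reconstruction degree tracks subject SNR", {
  coh <- fx_cohort()
  m <- fx_vae()
  mp <- fx_mapping()
  mesh <- fx_mesh3()
  msk <- !mesh$medial_mask
  scores <- vapply(coh$scans, function(s) {
    z <- encode(m, to_grid(s, mp))
    Xr <- from_grid(decode(m, z$mu), mp, nrow(mesh$vertices))
    fisher_mean(reconstruction_degree(s$values, Xr, msk))
  }, numeric(1))
  # higher per-subject noise multiplier = lower SNR -> lower score
  expect_lt(cor(scores, coh$manifest$noise_mult_subj), 0)
})
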