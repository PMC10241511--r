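test_that("icosphere meshes follow the subdivision recurrence", {
  m0 <- make_mesh(0)
  expect_equal(sum(m0$hemisphere == "L"), 12)
  expect_equal(nrow(m0$triangles), 2 * 20)
  m3 <- fx_mesh3()
  expect_equal(sum(m3$hemisphere == "L"), 642)   # 10 * 4^3 + 2
  expect_equal(nrow(m3$triangles), 2 * 1280)
  # vertices on the sphere of the requested radius
  ctr_l <- colMeans(m3$vertices[m3$hemisphere == "L", ])
  rad <- sqrt(rowSums(sweep(m3$vertices[m3$hemisphere == "L", ], 2, ctr_l)^2))
  expect_lt(max(abs(rad - 60)), 1e-6)
  # triangle indices valid, hemispheres contiguous
  expect_true(all(m3$triangles >= 1 & m3$triangles <= nrow(m3$vertices)))
  expect_equal(as.integer(table(m3$medial_mask)["TRUE"]), 2 * 33)
})

test_that("network maps are unit-norm, near-orthogonal, deterministic and smooth", {
  maps <- fx_maps()
  expect_equal(dim(maps), c(5, 1284))
  expect_equal(rowSums(maps^2), rep(1, 5), tolerance = 1e-10)
  G <- abs(tcrossprod(maps)); diag(G) <- 0
  expect_lt(max(G), 0.3)
  maps2 <- make_networks(fx_mesh3(), 5, 15, seed = 11, geo = fx_geo3())
  expect_identical(maps, maps2)
  # larger smoothing -> higher spatial lag-1 autocorrelation along edges
  edge_ac <- function(M) {
    e <- latentcortex:::mesh_edges(fx_mesh3())
    mean(vapply(seq_len(nrow(M)), function(k)
      cor(M[k, e[, 1]], M[k, e[, 2]]), numeric(1)))
  }
  rough <- make_networks(fx_mesh3(), 5, 4, seed = 11, geo = fx_geo3())
  expect_gt(edge_ac(fx_maps()), edge_ac(rough))
  expect_error(make_networks(fx_mesh3(), 2000, 10), "<= V")
})

test_that("cohorts reproduce exactly from seed and standardize each vertex", {
  coh <- fx_cohort()
  expect_length(coh$scans, 14)
  s1 <- coh$scans[[1]]$values
  expect_lt(max(abs(rowMeans(s1))), 1e-8)
  expect_lt(max(abs(rowMeans(s1^2) - 1)), 1e-6)
  coh2 <- simulate_cohort(fx_mesh3(), fx_truth(), n_subjects = 14, T = 160,
                          tr_seconds = 0.72, seed = 12, geo = fx_geo3())
  expect_identical(coh$scans[[5]]$values, coh2$scans[[5]]$values)
  expect_identical(coh$manifest$ages, coh2$manifest$ages)
  expect_true(all(coh$table$age_weeks >= 24.29 & coh$table$age_weeks <= 44.87))
})

test_that("noise-free single-network scans have rank one", {
  maps1 <- fx_maps()[1, , drop = FALSE]
  tr <- synthetic_truth(maps1, age_effect = matrix(0, 1, 1), noise_sd = 0,
                        structured_noise_sd = 0, subject_noise_sd_log = 0,
                        seed = 2)
  coh <- simulate_cohort(fx_mesh3(), tr, n_subjects = 1, T = 30, seed = 3)
  sv <- svd(coh$scans[[1]]$values, nu = 0, nv = 0)
  expect_lt(sv$d[2] / sv$d[1], 1e-8)
})

test_that("regressing sample source variance on age recovers the slope", {
  # gamma for source 1 is 0.05 per week (generator default); simulate the
  # source model for n = 200 subjects and regress per-subject sample source
  # variance on age. The fitted slope must lie in its own simulation CI
  # around gamma. (The vertex pipeline applies per-vertex standardization on
  # top of this, which rescales but does not create age structure; the
  # source-level slope is the quantity the generator promises.)
  tr <- fx_truth()
  set.seed(0)
  n <- 200
  ages <- runif(n, tr$age_range[1], tr$age_range[2])
  vars1 <- vapply(ages, function(a) {
    Sigma <- tr$base_cov + (a - tr$age0) * tr$age_effect
    Y <- latentcortex:::ar1_sources(Sigma, 400, tr$ar_coef)
    var(Y[1, ])
  }, numeric(1))
  fit <- lm(vars1 ~ ages)
  slope <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_gt(slope, 0)
  expect_lt(abs(slope - 0.05), 3 * se)
})

test_that("equal ages give exchangeable FC across subjects", {
  maps <- fx_maps()
  tr <- synthetic_truth(maps, seed = 5)
  coh <- simulate_cohort(fx_mesh3(), tr, n_subjects = 12, T = 200, seed = 6,
                         ages = rep(34.5, 12), geo = fx_geo3())
  vars <- t(vapply(coh$scans, function(s)
    apply(maps %*% s$values, 1, var), numeric(5)))
  # no age spread -> no systematic trend; all subjects' source variances agree
  # within sampling noise
  expect_lt(max(apply(vars, 2, sd) / colMeans(vars)), 0.5)
})

test_that("empirical vertex covariance converges to the model covariance", {
  # M' Sigma M + noise^2 I at T = 5000, relative Frobenius error < 10%
  maps <- make_networks(make_mesh(2), 3, 15, seed = 21)
  tr <- synthetic_truth(maps, age_effect = matrix(0, 3, 3) + diag(0, 3),
                        noise_sd = 0.4, structured_noise_sd = 0,
                        subject_noise_sd_log = 0, seed = 21)
  mesh2 <- make_mesh(2)
  coh <- simulate_cohort(mesh2, tr, n_subjects = 1, T = 5000, seed = 22,
                         ages = 34.5)
  V <- ncol(maps)
  proj <- t(maps) * sqrt(V / 3)
  Sig_model <- proj %*% diag(3) %*% t(proj) + 0.4^2 * diag(V)
  # the scan is standardized per vertex: compare correlation-scale versions
  Dm <- diag(1 / sqrt(diag(Sig_model)))
  Sig_model_c <- Dm %*% Sig_model %*% Dm
  Sig_emp <- tcrossprod(coh$scans[[1]]$values) / 5000
  err <- norm(Sig_emp - Sig_model_c, "F") / norm(Sig_model_c, "F")
  expect_lt(err, 0.10)
})

test_that("non-PSD age effects are rejected with the offending age", {
  maps1 <- fx_maps()[1:2, ]
  expect_error(synthetic_truth(maps1, age_effect = diag(c(0.2, 0)), seed = 1),
               "not PSD at age")
})

test_that("cohort profiles carry the acquisition differences", {
  p1 <- cohort_profile("dhcp_like")
  expect_equal(p1$T, 1400L); expect_equal(p1$tr_seconds, 0.392)
  p2 <- cohort_profile("dbi_like")
  expect_equal(p2$T, 150L); expect_equal(p2$tr_seconds, 2)
  expect_gt(p2$noise_mult, p1$noise_mult)
})
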