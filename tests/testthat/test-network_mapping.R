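rlap <- function(n) { u <- runif(n) - 0.5; -sign(u) * log(1 - 2 * abs(u)) / sqrt(2) }

test_that("latent concatenation preserves order and records boundaries", {
  z1 <- latent_ts(matrix(rnorm(4 * 100), 4, 100), subject_id = "a")
  z2 <- latent_ts(matrix(rnorm(4 * 150), 4, 150), subject_id = "b")
  cc <- concat_latents(list(z1, z2))
  expect_equal(dim(cc$Z), c(4, 250))
  expect_equal(cc$boundaries, c(0, 100, 250))
  expect_identical(cc$Z[, 1:100], z1$mu)
  one <- concat_latents(list(z1))
  expect_identical(one$Z, z1$mu)
  z3 <- latent_ts(matrix(rnorm(3 * 10), 3, 10))
  expect_error(concat_latents(list(z1, z3)), "dimensions differ")
  expect_error(concat_latents(list()), "empty")
})

test_that("temporal ICA recovers independent Laplacian sources from mixtures", {
  set.seed(23)
  k <- 5; Tn <- 4000
  S <- matrix(rlap(k * Tn), k, Tn)                  # super-Gaussian sources
  A <- matrix(rnorm(256 * k), 256, k)               # mix into 256 latent dims
  Zcat <- A %*% S + matrix(rnorm(256 * Tn, sd = 0.01), 256, Tn)  # high SNR
  nb <- temporal_ica(Zcat, n_components = 5, seed = 1)
  rec <- nb$timecourses
  m <- match_bases(S, rec)
  expect_true(all(m$abs_r >= 0.95))
  # same seed -> identical components
  nb2 <- temporal_ica(Zcat, n_components = 5, seed = 1)
  expect_identical(nb$unmixing, nb2$unmixing)
  # different seed -> identical up to permutation/sign at high SNR
  nb3 <- temporal_ica(Zcat, n_components = 5, seed = 99)
  m13 <- match_bases(nb$timecourses, nb3$timecourses)
  expect_true(all(m13$abs_r >= 0.99))
  # unmixing and mixing are mutual inverses on the retained subspace
  P <- nb$unmixing %*% nb$mixing
  expect_equal(P, diag(5), tolerance = 1e-6)
  expect_error(temporal_ica(Zcat[, 1:4], n_components = 5), "exceed")
})

test_that("a linear decoder makes basis_to_cortex proportional to D b", {
  set.seed(24)
  L <- 16; V <- 200
  D <- matrix(rnorm(V * L), V, L)
  dec_fun <- function(z) D %*% z
  b <- rnorm(L)
  map <- basis_to_cortex(b, dec_fun, n_scales = 1000, seed = 2)
  expect_gt(cor(map$values, as.vector(D %*% b)), 0.999)
  # 1-homogeneity up to Monte-Carlo error
  map3 <- basis_to_cortex(3 * b, dec_fun, n_scales = 1000, seed = 2)
  expect_gt(cor(map3$values, map$values), 0.99)
  # determinism given seed
  expect_identical(basis_to_cortex(b, dec_fun, seed = 7)$values,
                   basis_to_cortex(b, dec_fun, seed = 7)$values)
})

test_that("Monte-Carlo maps through the trained decoder converge in n_scales", {
  m <- fx_vae(); mp <- fx_mapping(); mesh <- fx_mesh3()
  set.seed(25)
  b <- rnorm(64)
  m1 <- basis_to_cortex(b, m, mp, nrow(mesh$vertices), n_scales = 1000, seed = 3)
  m2 <- basis_to_cortex(b, m, mp, nrow(mesh$vertices), n_scales = 100000, seed = 4)
  nm <- !mesh$medial_mask
  expect_gt(cor(m1$values[nm], m2$values[nm]), 0.99)
})

test_that("sign fixing puts the strongest vertex in the activation state", {
  expect_equal(fix_sign(c(-3, 1))$values, c(3, -1))
  expect_equal(fix_sign(c(3, -1))$values, c(3, -1))
  # tie |+2| vs |-2|: lower index wins (here the -2 comes first -> flip)
  expect_equal(fix_sign(c(-2, 2))$values, c(2, -2))
  expect_equal(fix_sign(c(2, -2))$values, c(2, -2))
  # idempotent
  m <- fix_sign(c(-1, 5, -7))
  expect_identical(fix_sign(m)$values, m$values)
  expect_warning(z <- fix_sign(c(0, 0)), "all-zero")
  expect_equal(z$values, c(0, 0))
})

test_that("thresholding zeroes sub-threshold vertices, monotone in fraction", {
  m <- threshold_map(c(1, -0.1, 0.2), fraction = 0.15)
  expect_equal(m$values, c(1, 0, 0.2))
  expect_equal(threshold_map(c(1, -0.1, 0.2), 0)$values, c(1, -0.1, 0.2))
  v <- rnorm(50)
  n_kept <- vapply(c(0, 0.15, 0.5, 0.9), function(f)
    sum(threshold_map(v, f)$values != 0), numeric(1))
  expect_true(all(diff(n_kept) <= 0))
  expect_equal(formals(threshold_map)$fraction, 0.15)
})

test_that("base matching recovers signed permutations and stays low under the null", {
  set.seed(26)
  A <- matrix(rnorm(5 * 300), 5, 300)
  perm <- c(3, 1, 5, 2, 4); sgn <- c(1, -1, 1, -1, -1)
  B <- A[perm, ] * sgn
  m <- match_bases(A, B)
  expect_true(all(m$abs_r > 0.999))
  expect_true(all(m$a == perm[m$b]))   # pair (a, b) iff row a = B row b source
  # greedy agrees with the exhaustive optimal assignment for k <= 6
  mo <- match_bases(A, B, method = "optimal")
  expect_true(all(mo$a == perm[mo$b]))
  # random orthogonal bases in high dimension: mean matched |r| small
  Q1 <- qr.Q(qr(matrix(rnorm(256 * 30), 256, 30)))
  Q2 <- qr.Q(qr(matrix(rnorm(256 * 30), 256, 30)))
  mn <- match_bases(t(Q1), t(Q2))
  expect_lt(mean(mn$abs_r), 0.3)
  expect_error(match_bases(A, B[1:3, ]), "counts differ")
})

test_that("reproducibility curves separate shared-truth from different-truth cohorts", {
  # same concatenated latents vs themselves, same seed -> similarity 1 at all k
  set.seed(27)
  Z <- matrix(rlap(8 * 800), 8, 800)
  A <- matrix(rnorm(20 * 8), 20, 8)
  Zc <- A %*% Z
  rc <- reproducibility_curve(list(a = Zc, b = Zc), n_components = 4,
                              n_seeds = 2, top_k = c(1, 3), seed = 31)
  expect_equal(rc$mean_abs_r, rep(1, nrow(rc)), tolerance = 1e-6)
})
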