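test_that("latent FC matches direct covariance computation", {
  set.seed(14)
  # 3 series with a specified covariance, long T -> sample matrix near truth
  Sig <- matrix(c(2, 0.8, -0.5, 0.8, 1, 0.2, -0.5, 0.2, 1.5), 3, 3)
  L <- chol(Sig)
  Z <- t(L) %*% matrix(rnorm(3 * 50000), 3, 50000)
  fc <- latent_fc(Z, "covariance")
  expect_lt(norm(fc$matrix - Sig, "F") / norm(Sig, "F"), 0.02)
  expect_equal(fc$vector, fc$matrix[upper.tri(fc$matrix)])
  # duplicated series: cov(i, j) = var(i)
  Z2 <- rbind(Z[1, ], Z[1, ], Z[2, ])
  fc2 <- latent_fc(Z2)
  expect_equal(fc2$matrix[1, 2], fc2$matrix[1, 1])
  # independent standardized series: off-diagonals near zero
  Z3 <- matrix(rnorm(4 * 10000), 4)
  fc3 <- latent_fc(Z3, "correlation")
  off <- fc3$matrix[upper.tri(fc3$matrix)]
  expect_lt(max(abs(off)), 0.05)
  expect_true(all(diag(fc3$matrix) == 1))
  expect_error(latent_fc(Z[, 1:2]), "T >= 3")
})

test_that("feature selection is exact for perfect features and calibrated under the null", {
  set.seed(15)
  n <- 60
  ages <- runif(n, 25, 44)
  F <- cbind(ages, matrix(rnorm(n * 20), n, 20))
  sel <- select_features(F, ages)
  expect_true(sel$mask[1])
  expect_equal(sel$r[1], 1, tolerance = 1e-12)
  # defaults: fdr alpha 0.05; uncorrected variant alpha 0.01
  expect_equal(sel$alpha, 0.05)
  expect_equal(select_features(F, ages, "uncorrected")$alpha, 0.01)
  # zero-variance feature excluded with warning
  Fz <- cbind(F, 0)
  expect_warning(selz <- select_features(Fz, ages), "zero-variance")
  expect_false(selz$mask[ncol(Fz)])
  # null calibration: family-wise any-selection rate under BH <= alpha
  # (1000 replicates, 500 features, n = 100)
  nrep <- 1000
  hits <- 0L
  set.seed(16)
  for (i in seq_len(nrep)) {
    a <- rnorm(100)
    Fn <- matrix(rnorm(100 * 500), 100, 500)
    r <- as.vector(cor(Fn, a))
    tt <- r * sqrt(98 / (1 - r^2))
    p <- 2 * pt(-abs(tt), 98)
    hits <- hits + any(p.adjust(p, "BH") < 0.05)
  }
  rate <- hits / nrep
  expect_lte(rate, 0.05 + 2.6 * sqrt(0.05 * 0.95 / nrep))  # MC margin
})

test_that("linear SVR learns realizable functions and handles degenerate targets", {
  set.seed(17)
  f <- runif(60, 0, 10)
  ages <- 2 * f + 1
  fit <- fit_rsvm(matrix(f[1:40]), ages[1:40])
  pred <- predict(fit, matrix(f[41:60]))
  expect_lt(max(abs(pred - ages[41:60])), 0.1 + 1e-3)  # within epsilon
  # constant ages -> predicts the constant
  fitc <- fit_rsvm(matrix(f[1:10]), rep(40, 10))
  expect_equal(predict(fitc, matrix(c(1, 5))), c(40, 40))
  expect_error(fit_rsvm(matrix(numeric(0), 0, 1), numeric(0)), "subjects")
  expect_error(fit_rsvm(matrix(0, 3, 0), rep(1, 3)), "empty feature set")
})

test_that("bias adjustment inverts affine prediction bias exactly", {
  ages_val <- c(30, 35, 40, 28, 42)
  # unbiased predictions -> identity adjuster
  adj0 <- bias_adjust(ages_val, ages_val)
  expect_equal(adj0$a, 1, tolerance = 1e-10)
  expect_equal(adj0$b, 0, tolerance = 1e-10)
  # pred = 0.5 * age + 20 -> adjusted test predictions equal truth exactly
  pred <- 0.5 * ages_val + 20
  adj <- bias_adjust(pred, ages_val)
  test_ages <- c(33, 39)
  expect_equal(adjust_predictions(adj, 0.5 * test_ages + 20), test_ages,
               tolerance = 1e-10)
  # pred = age - 2 -> adjuster adds 2
  adj2 <- bias_adjust(ages_val - 2, ages_val)
  expect_equal(adjust_predictions(adj2, 10), 12, tolerance = 1e-10)
  expect_error(bias_adjust(rep(1, 5), ages_val), "constant")
  expect_error(bias_adjust(1:2, 1:2), ">= 3")
  # adjustment never degrades validation MAE when the bias is exactly affine
  biased <- 0.7 * ages_val + 9
  adj3 <- bias_adjust(biased, ages_val)
  expect_lte(mean(abs(adjust_predictions(adj3, biased) - ages_val)),
             mean(abs(biased - ages_val)) + 1e-12)
})

test_that("prediction metrics match their formulas", {
  m <- prediction_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$rmse, 0.8165, tolerance = 1e-4)
  expect_equal(m$mae, 0.6667, tolerance = 1e-4)
  expect_true(is.na(m$correlation))          # constant predictions
  y <- c(30, 35, 40)
  m1 <- prediction_metrics(y, y)
  expect_equal(unlist(m1[c("rmse", "mae", "r2", "correlation")]),
               c(rmse = 0, mae = 0, r2 = 1, correlation = 1))
  m2 <- prediction_metrics(y, y + 1)
  expect_equal(m2$mae, 1); expect_equal(m2$correlation, 1)
  expect_error(prediction_metrics(1:3, 1:2), "equal lengths")
})

test_that("global network strength sums masked edges and scales linearly", {
  v <- c(0.3, 0.5, -0.2)
  mask <- c(TRUE, TRUE, FALSE)
  expect_equal(global_network_strength(v, mask), 0.8)
  expect_equal(global_network_strength(2 * v, mask), 1.6)
  expect_error(global_network_strength(v, c(FALSE, FALSE, FALSE)), "positively")
})

test_that("cross-validated prediction recovers a clean linear relationship", {
  set.seed(18)
  n <- 60
  ages <- runif(n, 25, 44)
  F <- cbind(3 * ages - 10, matrix(rnorm(n * 30), n, 30))
  rep_ <- crossval_predict(F, ages, k = 10, repeats = 2, seed = 4)
  mae <- rep_$summary$mean[rep_$summary$metric == "mae"]
  expect_lt(mae, 0.2)                      # exact feature, noiseless
  expect_gt(rep_$pooled_correlation, 0.99)
  expect_gt(rep_$selected_feature_fraction, 0)
  expect_error(crossval_predict(F[1:10, ], ages[1:10]), "n >= 20")
})

test_that("split sizes follow the 76.5/13.5/10 protocol at cohort scale", {
  # at n = 409 the train/val/test split must be ~314/55/40
  n <- 409
  fold <- rep_len(1:10, n)
  test_n <- sum(fold == 1)
  rest <- n - test_n
  val_n <- round(0.15 * rest)
  expect_equal(test_n, 41)
  expect_equal(val_n, 55)
  expect_equal(rest - val_n, 313)
  # the implementation draws its validation split with the same proportions
  set.seed(19)
  ages <- runif(40, 25, 44)
  F <- cbind(ages + rnorm(40, 0, 0.5), matrix(rnorm(40 * 5), 40, 5))
  rep_ <- crossval_predict(F, ages, k = 10, repeats = 1, seed = 5)
  expect_s3_class(rep_, "prediction_report")
  expect_equal(rep_$k, 10)
})

test_that("cross-center transfer with a shared age mechanism beats chance", {
  set.seed(20)
  gen <- function(n, noise) {
    ages <- runif(n, 25, 44)
    F <- cbind(0.1 * ages + rnorm(n, 0, noise),
               0.05 * ages + rnorm(n, 0, noise),
               matrix(rnorm(n * 10), n, 10))
    list(F = F, ages = ages)
  }
  tr <- gen(80, 0.3)
  te <- gen(50, 0.6)   # different noise level, same mechanism
  rep_ <- cross_center_predict(tr$F, tr$ages, te$F, te$ages,
                               repeats = 10, seed = 6)
  mae <- rep_$summary$mean[rep_$summary$metric == "mae"]
  expect_lt(mae, rep_$chance_mae)
})
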