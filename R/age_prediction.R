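#' Latent functional connectivity
#'
#' FC of a latent timeseries: the sample covariance (or Pearson correlation)
#' matrix of the latent variables, plus its vectorized upper triangle
#' (diagonal excluded; length `L*(L-1)/2`, e.g. 32,640 for 256 latents).
#'
#' @param Z a `latent_ts` (or an L x T matrix).
#' @param mode `"covariance"` or `"correlation"`.
#' @return object of class `latent_fc` with `matrix` (L x L), `vector`
#'   (upper triangle), `mode` and the subject metadata.
#' @export
latent_fc <- function(Z, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  M <- if (inherits(Z, "latent_ts")) Z$mu else as.matrix(Z)
  if (ncol(M) < 3) stop("latent_fc: need T >= 3", call. = FALSE)
  Fm <- if (mode == "covariance") cov(t(M)) else {
    v <- apply(M, 1, sd)
    if (any(v < 1e-12))
      warning(sprintf("latent_fc: %d constant series -> NA correlations",
                      sum(v < 1e-12)), call. = FALSE)
    suppressWarnings(cor(t(M)))
  }
  structure(list(matrix = Fm, vector = Fm[upper.tri(Fm)], mode = mode,
                 subject_id = if (inherits(Z, "latent_ts")) Z$subject_id else NA,
                 session_id = if (inherits(Z, "latent_ts")) Z$session_id else NA,
                 age_weeks = if (inherits(Z, "latent_ts")) Z$age_weeks else NA),
            class = "latent_fc")
}

## stack per-subject FC vectors into subjects x features
fc_feature_matrix <- function(fc_list) {
  t(vapply(fc_list, function(f) f$vector, numeric(length(fc_list[[1]]$vector))))
}

#' Age-association feature selection
#'
#' Correlates every feature with age on the training subjects and thresholds
#' by Benjamini-Hochberg FDR (default alpha 0.05) or by uncorrected p (the
#' single-group variant, alpha 0.01). Zero-variance features are excluded with
#' a warning.
#'
#' @param F subjects x features matrix.
#' @param ages subject ages (length `nrow(F)` >= 4).
#' @param method `"fdr"` or `"uncorrected"`.
#' @param alpha selection threshold (default 0.05 for fdr, 0.01 for
#'   uncorrected).
#' @return list with `mask` (logical per feature), `r`, `p`, `p_adj`,
#'   `alpha`, `method`.
#' @export
select_features <- function(F, ages, method = c("fdr", "uncorrected"),
                            alpha = NULL) {
  method <- match.arg(method)
  if (is.null(alpha)) alpha <- if (method == "fdr") 0.05 else 0.01
  n <- nrow(F)
  if (n < 4) stop("select_features: need >= 4 subjects", call. = FALSE)
  sds <- apply(F, 2, sd)
  zv <- sds < 1e-12
  if (any(zv))
    warning(sprintf("select_features: %d zero-variance feature(s) excluded",
                    sum(zv)), call. = FALSE)
  r <- rep(NA_real_, ncol(F))
  r[!zv] <- suppressWarnings(as.vector(cor(F[, !zv, drop = FALSE], ages)))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-15))
  p <- 2 * pt(-abs(tt), n - 2)
  p_adj <- if (method == "fdr") p.adjust(p, "BH") else p
  mask <- !is.na(p_adj) & p_adj < alpha
  list(mask = mask, r = r, p = p, p_adj = p_adj, alpha = alpha, method = method)
}

#' Linear support-vector regression of age on FC features
#'
#' Fits a linear epsilon-insensitive SVR (C = 1, epsilon = 0.1 by default) on
#' the selected features, standardized by the training statistics supplied.
#'
#' @param F_selected training subjects x selected features.
#' @param ages training ages.
#' @param cost regularization C.
#' @param epsilon insensitivity width.
#' @return object of class `rsvm_fit` with the model and the training
#'   standardization; predict with [predict.rsvm_fit()].
#' @export
fit_rsvm <- function(F_selected, ages, cost = 1, epsilon = 0.1) {
  F_selected <- as.matrix(F_selected)
  if (ncol(F_selected) < 1) stop("fit_rsvm: empty feature set", call. = FALSE)
  if (nrow(F_selected) < 2) stop("fit_rsvm: need >= 2 subjects", call. = FALSE)
  ctr <- colMeans(F_selected)
  scl <- apply(F_selected, 2, sd); scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(F_selected, 2, ctr), 2, scl, "/")
  if (var(ages) < 1e-20) {
    fit <- NULL  # degenerate: constant target
  } else {
    fit <- e1071::svm(Xs, ages, type = "eps-regression", kernel = "linear",
                      cost = cost, epsilon = epsilon, scale = FALSE)
  }
  structure(list(fit = fit, center = ctr, scale = scl,
                 const = if (is.null(fit)) ages[1] else NA_real_),
            class = "rsvm_fit")
}

#' @param object an `rsvm_fit`.
#' @param newdata matrix of features (same columns as training).
#' @param ... unused.
#' @rdname fit_rsvm
#' @export
predict.rsvm_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(object$fit)) return(rep(object$const, nrow(newdata)))
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.vector(predict(object$fit, Xs))
}

#' Prediction-bias adjustment
#'
#' Regresses actual on predicted age in the validation set
#' (`actual = a * predicted + b`) and returns the affine adjuster
#' `p -> a*p + b` applied to test predictions. Exactly inverts an affine
#' prediction bias.
#'
#' @param predictions_val,ages_val validation predictions and actual ages
#'   (length >= 3; predictions must not be constant).
#' @return object of class `bias_adjuster` (callable via
#'   [adjust_predictions()]) with slope `a` and intercept `b`.
#' @export
bias_adjust <- function(predictions_val, ages_val) {
  if (length(predictions_val) < 3)
    stop("bias_adjust: need >= 3 validation subjects", call. = FALSE)
  if (sd(predictions_val) < 1e-12)
    stop("bias_adjust: constant predictions", call. = FALSE)
  fit <- lm(ages_val ~ predictions_val)
  structure(list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1])),
            class = "bias_adjuster")
}

#' @param adjuster a `bias_adjuster`.
#' @param predictions test predictions.
#' @rdname bias_adjust
#' @export
adjust_predictions <- function(adjuster, predictions) {
  adjuster$a * predictions + adjuster$b
}

#' Prediction performance metrics
#'
#' RMSE, MAE, squared Pearson correlation (r^2) and Pearson correlation
#' between actual and predicted values. Correlation is `NA` for constant
#' predictions.
#'
#' @param y actual values.
#' @param yhat predicted values.
#' @return list with `rmse`, `mae`, `r2`, `correlation`.
#' @export
prediction_metrics <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 2)
    stop("prediction_metrics: need equal lengths >= 2", call. = FALSE)
  e <- y - yhat
  r <- if (sd(yhat) < 1e-12 || sd(y) < 1e-12) NA_real_ else cor(y, yhat)
  list(rmse = sqrt(mean(e^2)), mae = mean(abs(e)), r2 = r^2, correlation = r)
}

#' Global network strength
#'
#' Sum of a subject's FC values over the significant, positively
#' age-correlated edges: the single-feature summary used when feature spaces
#' must be comparable across acquisitions.
#'
#' @param F_vector one subject's FC feature vector.
#' @param selected_positive_mask logical mask of significant edges with
#'   positive age correlation.
#' @return scalar strength.
#' @export
global_network_strength <- function(F_vector, selected_positive_mask) {
  if (!any(selected_positive_mask))
    stop("global_network_strength: no positively age-correlated significant edges",
         call. = FALSE)
  sum(F_vector[selected_positive_mask])
}

## mean-age (chance) MAE of a set of ages: predictor that always outputs the
## training mean
chance_mae <- function(ages) mean(abs(ages - mean(ages)))

#' Tenfold cross-validated age prediction
#'
#' The full prediction protocol: per repeat, scans are shuffled into 10 folds;
#' each fold serves once as the 10% test set while the remaining 90% is split
#' into training (76.5% of all scans) and validation (13.5%). Features are
#' selected (FDR by default) and the SVR fitted on the training portion only;
#' the bias adjuster is fitted on the validation predictions; adjusted metrics
#' are computed on the held-out test fold. Folds with an empty selection are
#' skipped and logged.
#'
#' @param F subjects x features matrix (e.g. from [latent_fc()] vectors).
#' @param ages subject ages (n >= 20).
#' @param k folds (default 10).
#' @param repeats independent repetitions (default 100).
#' @param seed RNG seed.
#' @param select_method,alpha passed to [select_features()].
#' @param cost,epsilon passed to [fit_rsvm()].
#' @return object of class `prediction_report`: per-fold metrics, their
#'   mean +/- sd, pooled actual/predicted pairs and their correlation, chance
#'   MAE, selected-feature fraction (%), skipped folds and seeds.
#' @export
crossval_predict <- function(F, ages, k = 10L, repeats = 100L, seed = 1L,
                             select_method = "fdr", alpha = NULL,
                             cost = 1, epsilon = 0.1) {
  n <- nrow(F)
  if (n < 20) stop("crossval_predict: need n >= 20", call. = FALSE)
  stopifnot(length(ages) == n)
  with_seed(seed, {
    rows <- list(); skipped <- 0L
    pooled_y <- c(); pooled_yhat <- c()
    sel_frac <- c()
    for (rep_i in seq_len(repeats)) {
      fold_id <- sample(rep_len(seq_len(k), n))
      for (fold in seq_len(k)) {
        test <- which(fold_id == fold)
        rest <- which(fold_id != fold)
        n_val <- max(3L, round(0.15 * length(rest)))
        val <- sample(rest, n_val)
        train <- setdiff(rest, val)
        sel <- select_features(F[train, , drop = FALSE], ages[train],
                               method = select_method, alpha = alpha)
        if (!any(sel$mask)) { skipped <- skipped + 1L; next }
        sel_frac <- c(sel_frac, 100 * mean(sel$mask))
        fit <- fit_rsvm(F[train, sel$mask, drop = FALSE], ages[train],
                        cost = cost, epsilon = epsilon)
        pv <- predict(fit, F[val, sel$mask, drop = FALSE])
        adj <- tryCatch(bias_adjust(pv, ages[val]), error = function(e) NULL)
        pt_ <- predict(fit, F[test, sel$mask, drop = FALSE])
        if (!is.null(adj)) pt_ <- adjust_predictions(adj, pt_)
        m <- prediction_metrics(ages[test], pt_)
        rows[[length(rows) + 1L]] <-
          data.frame(repeat_i = rep_i, fold = fold, rmse = m$rmse, mae = m$mae,
                     r2 = m$r2, correlation = m$correlation)
        pooled_y <- c(pooled_y, ages[test]); pooled_yhat <- c(pooled_yhat, pt_)
      }
    }
    if (!length(rows)) stop("crossval_predict: all folds skipped", call. = FALSE)
    per_fold <- do.call(rbind, rows)
    structure(list(
      per_fold = per_fold,
      summary = data.frame(
        metric = c("rmse", "mae", "r2", "correlation"),
        mean = vapply(c("rmse", "mae", "r2", "correlation"),
                      function(m) mean(per_fold[[m]], na.rm = TRUE), numeric(1)),
        sd = vapply(c("rmse", "mae", "r2", "correlation"),
                    function(m) sd(per_fold[[m]], na.rm = TRUE), numeric(1))),
      pooled = data.frame(actual = pooled_y, predicted = pooled_yhat),
      pooled_correlation = suppressWarnings(cor(pooled_y, pooled_yhat)),
      chance_mae = chance_mae(ages),
      selected_feature_fraction = mean(sel_frac),
      n = n, k = k, repeats = repeats, seed = seed, skipped = skipped),
      class = "prediction_report")
  })
}

#' @exportS3Method base::print
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> n=%d, %d-fold x %d repeats (%d folds skipped)\n",
              x$n, x$k, x$repeats, x$skipped))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  cat(sprintf("  chance MAE   %.4f\n  selected features %.2f%%\n",
              x$chance_mae, x$selected_feature_fraction))
  invisible(x)
}

#' Cross-center age prediction
#'
#' Transfer protocol between acquisitions: per repeat, 50% of the training
#' cohort's scans are drawn; 85% of the draw fits the single-feature model
#' (global network strength over significant positive edges, ordinary linear
#' regression) and 15% serves as validation for the bias adjuster; the
#' adjusted model is then evaluated on the full test cohort.
#'
#' @param F_train,ages_train training-center features and ages.
#' @param F_test,ages_test test-center features and ages.
#' @param repeats repetitions (default 100).
#' @param seed RNG seed.
#' @param select_method,alpha passed to [select_features()].
#' @return a `prediction_report` (per-repeat metrics on the test cohort).
#' @export
cross_center_predict <- function(F_train, ages_train, F_test, ages_test,
                                 repeats = 100L, seed = 1L,
                                 select_method = "fdr", alpha = NULL) {
  with_seed(seed, {
    rows <- list(); skipped <- 0L
    pooled_y <- c(); pooled_yhat <- c()
    for (rep_i in seq_len(repeats)) {
      draw <- sample(nrow(F_train), max(4L, round(0.5 * nrow(F_train))))
      n_val <- max(3L, round(0.15 * length(draw)))
      val <- sample(draw, n_val)
      fit_set <- setdiff(draw, val)
      sel <- select_features(F_train[fit_set, , drop = FALSE], ages_train[fit_set],
                             method = select_method, alpha = alpha)
      pos_mask <- sel$mask & !is.na(sel$r) & sel$r > 0
      if (!any(pos_mask)) { skipped <- skipped + 1L; next }
      gns <- function(Fm) apply(Fm, 1, global_network_strength, pos_mask)
      df_fit <- data.frame(g = gns(F_train[fit_set, , drop = FALSE]),
                           age = ages_train[fit_set])
      lmfit <- lm(age ~ g, data = df_fit)
      pv <- predict(lmfit, data.frame(g = gns(F_train[val, , drop = FALSE])))
      adj <- tryCatch(bias_adjust(pv, ages_train[val]), error = function(e) NULL)
      pt_ <- predict(lmfit, data.frame(g = gns(F_test)))
      if (!is.null(adj)) pt_ <- adjust_predictions(adj, pt_)
      m <- prediction_metrics(ages_test, pt_)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_i = rep_i, fold = 1L, rmse = m$rmse, mae = m$mae,
                   r2 = m$r2, correlation = m$correlation)
      pooled_y <- c(pooled_y, ages_test); pooled_yhat <- c(pooled_yhat, pt_)
    }
    if (!length(rows))
      stop("cross_center_predict: no repeat produced a model", call. = FALSE)
    per_fold <- do.call(rbind, rows)
    structure(list(
      per_fold = per_fold,
      summary = data.frame(
        metric = c("rmse", "mae", "r2", "correlation"),
        mean = vapply(c("rmse", "mae", "r2", "correlation"),
                      function(m) mean(per_fold[[m]], na.rm = TRUE), numeric(1)),
        sd = vapply(c("rmse", "mae", "r2", "correlation"),
                    function(m) sd(per_fold[[m]], na.rm = TRUE), numeric(1))),
      pooled = data.frame(actual = pooled_y, predicted = pooled_yhat),
      pooled_correlation = suppressWarnings(cor(pooled_y, pooled_yhat)),
      chance_mae = chance_mae(ages_test),
      selected_feature_fraction = NA_real_,
      n = nrow(F_test), k = 1L, repeats = repeats, seed = seed,
      skipped = skipped),
      class = "prediction_report")
  })
}
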