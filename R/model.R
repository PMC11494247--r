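# Gradient-boosted classification of platinum resistance with stratified
# 5-fold cross-validation and the full evaluation panel (MSE, RMSE, logloss,
# mean per-class error, AUC, AUCPR, Gini, R^2), normalized gain importances,
# calibration and gains/lift tables, and a learning curve.

model_groups <- c("conventional", "heterogeneity", "integrated")
texture_indicator_names <- c("cSE", "cluDev", "cludiss")

#' Specify a model group and its learner
#'
#' Feature groups: `conventional` = clinical covariates + the 104
#' conventional indicators; `heterogeneity` = clinical + the 3 texture
#' indicators; `integrated` = the union (clinical + all 107).
#'
#' @param group One of `"conventional"`, `"heterogeneity"`, `"integrated"`.
#' @param features Character vector of feature columns; `NULL` selects the
#'   group's default from the supplied table at fit time.
#' @param n_trees,max_depth,learn_rate,subsample,min_obs,lambda Boosting
#'   hyperparameters.
#' @param cv_folds Number of CV folds (>= 2; default 5).
#' @param seed RNG seed for fold assignment and row subsampling.
#' @return A `model_spec`.
#' @export
model_spec <- function(group = model_groups, features = NULL, n_trees = 150,
                       max_depth = 3, learn_rate = 0.1, subsample = 0.8,
                       min_obs = 5, lambda = 1, cv_folds = 5, seed = 1) {
  group <- match.arg(group)
  if (cv_folds < 2) stopf("cv_folds must be >= 2")
  structure(list(group = group, features = features, n_trees = n_trees,
                 max_depth = max_depth, learn_rate = learn_rate,
                 subsample = subsample, min_obs = min_obs, lambda = lambda,
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "model_spec")
}

#' Default feature set of a model group
#'
#' Everything that is not an indicator, `patient_id` or `resistance` counts
#' as a clinical covariate.
#'
#' @param group Model group name.
#' @param cols Available column names.
#' @return Character vector of feature names.
#' @export
group_features <- function(group, cols) {
  conv <- as.vector(outer(conv_features, conv_stats, paste, sep = "_"))
  tex <- texture_indicator_names
  clinical <- setdiff(cols, c(conv, tex, "patient_id", "resistance"))
  switch(group,
         conventional = c(clinical, intersect(conv, cols)),
         heterogeneity = c(clinical, intersect(tex, cols)),
         integrated = c(clinical, intersect(c(conv, tex), cols)))
}

as_feature_matrix <- function(table, features) {
  miss <- setdiff(features, colnames(table))
  if (length(miss))
    stopf("missing feature column(s): %s", paste(head(miss, 5), collapse = ", "))
  m <- as.matrix(as.data.frame(lapply(table[features], as.numeric)))
  colnames(m) <- features
  m
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling.
#' @param pred Scores/probabilities. @param labels 0/1.
#' @export
auc_roc <- function(pred, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(pred, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve (average precision over distinct
# score cut-offs, ties grouped).
auc_pr <- function(pred, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0) return(NA_real_)
  ord <- order(pred, decreasing = TRUE)
  p <- pred[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(y); n <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; n <- n[last]
  recall <- tp / n1
  precision <- tp / n
  dr <- diff(c(0, recall))
  sum(dr * precision)
}

#' Evaluate the full metric panel
#'
#' @param pred Predicted probabilities in [0,1].
#' @param labels Binary 0/1 labels.
#' @param threshold Classification threshold for the per-class error
#'   (default 0.5).
#' @return Named list: `mse`, `rmse`, `logloss`, `mean_per_class_error`,
#'   `auc`, `aucpr`, `gini` (= 2*AUC - 1), `r2` (on the probability scale
#'   against the 0/1 labels).
#' @export
evaluate <- function(pred, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  mse <- mean((pred - labels)^2)
  eps <- 1e-15
  pc <- pmin(pmax(pred, eps), 1 - eps)
  logloss <- -mean(labels * log(pc) + (1 - labels) * log(1 - pc))
  cls <- as.numeric(pred >= threshold)
  err1 <- if (any(labels == 1)) mean(cls[labels == 1] != 1) else NA_real_
  err0 <- if (any(labels == 0)) mean(cls[labels == 0] != 0) else NA_real_
  auc <- auc_roc(pred, labels)
  list(mse = mse, rmse = sqrt(mse), logloss = logloss,
       mean_per_class_error = mean(c(err1, err0), na.rm = TRUE),
       auc = auc, aucpr = auc_pr(pred, labels), gini = 2 * auc - 1,
       r2 = 1 - mse / mean((labels - mean(labels))^2))
}

# Seed-deterministic stratified fold assignment.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

gbt_fit <- function(X, y, spec, seed) {
  cpp_gbt_fit(X, as.numeric(y), spec$n_trees, spec$max_depth,
              spec$learn_rate, spec$subsample, spec$min_obs, spec$lambda,
              seed)
}

gbt_predict <- function(fit, X) {
  plogis(cpp_gbt_margin(fit$trees, fit$f0, X))
}

#' Fit a gradient-boosted model with stratified cross-validation
#'
#' Stratified seeded k-fold CV (default 5-fold); the report carries the
#' Table-3-style metric panel for the training fit and for the pooled
#' out-of-fold predictions, per-fold accuracy/specificity mean +/- SD,
#' normalized variable importances, calibration and gains/lift tables and a
#' learning curve. The final model is refitted on all rows. Missing feature
#' values are passed to the learner's native missing handling, never imputed.
#'
#' @param spec A [model_spec()].
#' @param table data.frame of indicators/covariates (may contain NA).
#' @param labels Binary 0/1 outcome (both classes required; >= 20 rows).
#' @return `model_report`: list with `spec`, `features`, `model`, `metrics`
#'   (`train`, `cv`, `per_fold`), `cv_accuracy`, `cv_specificity`,
#'   `importance`, `calibration`, `gains_lift`, `learning_curve`,
#'   `cv_pred` and `folds`.
#' @export
fit_cv <- function(spec, table, labels) {
  labels <- as.numeric(labels)
  if (length(labels) != nrow(table))
    stopf("labels length must match table rows")
  if (nrow(table) < 20) stopf("need at least 20 patients")
  if (length(unique(labels)) < 2)
    stopf("degenerate labels: only one class present")
  features <- spec$features %||% group_features(spec$group, colnames(table))
  X <- as_feature_matrix(table, features)
  folds <- stratified_folds(labels, spec$cv_folds, spec$seed)
  cv_pred <- numeric(length(labels))
  per_fold <- vector("list", spec$cv_folds)
  acc <- spe <- numeric(spec$cv_folds)
  for (f in seq_len(spec$cv_folds)) {
    tr <- folds != f
    fit_f <- gbt_fit(X[tr, , drop = FALSE], labels[tr], spec,
                     derive_seed(spec$seed, f))
    p <- gbt_predict(fit_f, X[!tr, , drop = FALSE])
    cv_pred[!tr] <- p
    per_fold[[f]] <- evaluate(p, labels[!tr])
    cls <- as.numeric(p >= 0.5)
    acc[f] <- mean(cls == labels[!tr])
    spe[f] <- if (any(labels[!tr] == 0)) mean(cls[labels[!tr] == 0] == 0)
      else NA_real_
  }
  model <- gbt_fit(X, labels, spec, derive_seed(spec$seed, 0L))
  train_pred <- gbt_predict(model, X)
  report <- structure(list(
    spec = spec, features = features, model = model,
    metrics = list(train = evaluate(train_pred, labels),
                   cv = evaluate(cv_pred, labels),
                   per_fold = per_fold),
    cv_accuracy = c(mean = mean(acc), sd = sd(acc)),
    cv_specificity = c(mean = mean(spe, na.rm = TRUE),
                       sd = sd(spe, na.rm = TRUE)),
    importance = normalize_importance(model$importance, features),
    calibration = calibration_curve(cv_pred, labels),
    gains_lift = gains_lift(cv_pred, labels),
    learning_curve = learning_curve(model, X, labels),
    cv_pred = cv_pred, folds = folds), class = "model_report")
  report
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report %s> train AUC %.3f | CV AUC %.3f (acc %.3f +/- %.3f)\n",
              x$spec$group, x$metrics$train$auc, x$metrics$cv$auc,
              x$cv_accuracy["mean"], x$cv_accuracy["sd"]))
  invisible(x)
}

normalize_importance <- function(imp, features) {
  names(imp) <- features
  mx <- max(imp)
  if (mx > 0) imp <- imp / mx
  sort(imp, decreasing = TRUE)
}

#' Normalized variable importances of a fitted report
#'
#' Gain-based importances scaled so the largest equals 1, descending.
#' @param report A [fit_cv()] report.
#' @export
variable_importance <- function(report) {
  report$importance
}

#' Calibration table
#'
#' Per equal-width probability bin: mean predicted probability vs observed
#' event rate. Empty bins are dropped (with a message).
#'
#' @param pred Probabilities. @param labels 0/1. @param n_bins Default 10.
#' @return data.frame: bin, n, mean_pred, obs_rate.
#' @export
calibration_curve <- function(pred, labels, n_bins = 10) {
  br <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(pred, br, include.lowest = TRUE, labels = FALSE)
  rows <- lapply(seq_len(n_bins), function(b) {
    idx <- which(bin == b)
    if (!length(idx)) return(NULL)
    data.frame(bin = b, n = length(idx), mean_pred = mean(pred[idx]),
               obs_rate = mean(labels[idx]))
  })
  empty <- sum(vapply(rows, is.null, logical(1)))
  if (empty) message(sprintf("calibration: %d empty bin(s) dropped", empty))
  do.call(rbind, rows)
}

#' Gains/lift table
#'
#' Rows sorted by decreasing predicted probability and split into
#' `n_quantiles` groups: per-group capture rate, cumulative capture rate,
#' lift and cumulative lift.
#'
#' @param pred Probabilities. @param labels 0/1. @param n_quantiles Default 10.
#' @return data.frame: quantile, n, n_pos, capture_rate, cum_capture_rate,
#'   lift, cum_lift.
#' @export
gains_lift <- function(pred, labels, n_quantiles = 10) {
  ord <- order(pred, decreasing = TRUE)
  y <- labels[ord]
  n <- length(y)
  grp <- ceiling(seq_len(n) / n * n_quantiles)
  total_pos <- sum(y)
  prev <- total_pos / n
  rows <- lapply(seq_len(n_quantiles), function(q) {
    idx <- which(grp == q)
    if (!length(idx)) return(NULL)
    np <- sum(y[idx])
    cum_idx <- which(grp <= q)
    data.frame(quantile = q, n = length(idx), n_pos = np,
               capture_rate = np / total_pos,
               cum_capture_rate = sum(y[cum_idx]) / total_pos,
               lift = (np / length(idx)) / prev,
               cum_lift = (sum(y[cum_idx]) / length(cum_idx)) / prev)
  })
  do.call(rbind, rows)
}

# Training logloss as a function of boosting rounds (every `by` trees).
learning_curve <- function(model, X, labels, by = 10) {
  steps <- unique(c(seq(by, length(model$trees), by = by),
                    length(model$trees)))
  eps <- 1e-15
  ll <- vapply(steps, function(t) {
    p <- plogis(cpp_gbt_margin(model$trees[seq_len(t)], model$f0, X))
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(labels * log(p) + (1 - labels) * log(1 - p))
  }, numeric(1))
  data.frame(trees = steps, train_logloss = ll)
}

#' Bootstrap confidence interval for the AUC
#'
#' Seeded nonparametric bootstrap (resampling rows with replacement).
#'
#' @param pred Probabilities. @param labels 0/1.
#' @param n_boot Resamples (default 2000). @param level Default 0.95.
#' @param seed RNG seed.
#' @return Named numeric: auc, lower, upper.
#' @export
auc_ci <- function(pred, labels, n_boot = 2000, level = 0.95, seed = 1) {
  n <- length(pred)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    auc_roc(pred[idx], labels[idx])
  }, numeric(1)))
  qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  c(auc = auc_roc(pred, labels), lower = unname(qs[1]), upper = unname(qs[2]))
}

#' Write a model report to disk
#'
#' Metrics as JSON (if jsonlite is installed) plus CSV tables for
#' importances, calibration, gains/lift and the learning curve.
#'
#' @param report A [fit_cv()] report.
#' @param dir Output directory.
#' @export
write_model_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(group = report$spec$group,
           train = report$metrics$train, cv = report$metrics$cv,
           cv_accuracy = as.list(report$cv_accuracy),
           cv_specificity = as.list(report$cv_specificity)),
      file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  write.csv(data.frame(feature = names(report$importance),
                       importance = as.numeric(report$importance)),
            file.path(dir, "importance.csv"), row.names = FALSE)
  write.csv(report$calibration, file.path(dir, "calibration.csv"),
            row.names = FALSE)
  write.csv(report$gains_lift, file.path(dir, "gains_lift.csv"),
            row.names = FALSE)
  write.csv(report$learning_curve, file.path(dir, "learning_curve.csv"),
            row.names = FALSE)
  invisible(dir)
}
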