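#' Train the Ki-67 SVM on a feature panel
#'
#' Radial-kernel support vector machine with cost 1, kernel width
#' 1/d on standardized features (the `scale` convention), class weights
#' inversely proportional to class sizes (the cohorts are imbalanced),
#' and Platt-type probability calibration so scores are interpretable as
#' the probability of the "high" class. Standardization parameters are
#' fit on the training data only and stored for prediction.
#'
#' @param data Tibble of numeric features (columns = panel).
#' @param labels Character vector "high"/"low".
#' @param cost SVM cost parameter.
#' @param gamma Kernel width; default 1/ncol after standardization.
#' @param seed Seed for the internal probability-calibration resampling.
#' @return A `ki67_svm` object with a [predict()] method returning
#'   P(high).
#' @export
fit_ki67_svm <- function(data, labels, cost = 1, gamma = NULL, seed = 1) {
  feats <- as.matrix(data[vapply(data, is.numeric, logical(1))])
  y <- factor(labels, levels = c("low", "high"))
  if (nlevels(droplevels(y)) < 2)
    stop("training requires both classes")
  ctr <- colMeans(feats)
  scl <- apply(feats, 2, sd)
  scl[scl == 0] <- 1
  x <- scale(feats, center = ctr, scale = scl)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  w <- length(y) / (2 * table(y))
  set.seed(seed)
  fit <- e1071::svm(x, y, kernel = "radial", cost = cost, gamma = gamma,
                    class.weights = w, probability = TRUE, scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl,
                 features = colnames(feats)), class = "ki67_svm")
}

#' @export
predict.ki67_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  x <- scale(x, center = object$center, scale = object$scale)
  pr <- predict(object$fit, x, probability = TRUE)
  unname(attr(pr, "probabilities")[, "high"])
}

#' Rank-based AUC with a DeLong confidence interval
#'
#' AUC as the two-sample rank statistic U/(n1 n0) (ties counted 1/2,
#' equivalent to the trapezoidal ROC area), with the asymptotic
#' DeLong-type variance from the positive- and negative-placement
#' components. Constant scores give AUC 0.5 with a degenerate-interval
#' warning.
#'
#' @param scores Numeric scores (higher = more "high").
#' @param labels Character/factor, "high" positive, "low" negative.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `auc`, `ci_lower`, `ci_upper`, `se`.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  pos <- scores[labels == "high"]
  neg <- scores[labels == "low"]
  n1 <- length(pos); n0 <- length(neg)
  stopifnot(n1 > 0, n0 > 0)
  if (max(scores) == min(scores))
    warning("constant scores: AUC 0.5 with a degenerate interval")
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(cmp)
  v10 <- rowMeans(cmp)           # placement of each positive
  v01 <- colMeans(cmp)           # placement of each negative
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(auc = auc,
                 ci_lower = max(0, auc - z * se),
                 ci_upper = min(1, auc + z * se),
                 se = se)
}

.confusion_metrics <- function(tp, fp, tn, fn) {
  tibble::tibble(
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Classification metrics of a confusion matrix
#'
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @return One-row tibble: accuracy, sensitivity, specificity, PPV, NPV.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) .confusion_metrics(tp, fp, tn, fn)

#' Youden-index operating point and its metrics
#'
#' Scans every observed score as a threshold (predict "high" when score
#' >= cutoff), picks the cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1 (ties resolved toward higher
#' specificity, then higher cutoff), and reports the five metrics of the
#' resulting confusion matrix.
#'
#' @param scores Numeric scores.
#' @param labels "high"/"low" labels.
#' @return One-row tibble: `cutoff`, `youden`, `tp`, `fp`, `tn`, `fn`,
#'   plus the five metrics.
#' @export
youden_metrics <- function(scores, labels) {
  stopifnot(any(labels == "high"), any(labels == "low"))
  thr <- sort(unique(scores))
  n1 <- sum(labels == "high"); n0 <- sum(labels == "low")
  stats <- vapply(thr, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == "high"); fp <- sum(pred & labels == "low")
    c(tp = tp, fp = fp)
  }, numeric(2))
  sens <- stats["tp", ] / n1
  spec <- (n0 - stats["fp", ]) / n0
  J <- sens + spec - 1
  best <- order(-J, -spec, -thr)[1]
  tp <- unname(stats["tp", best]); fp <- unname(stats["fp", best])
  fn <- n1 - tp; tn <- n0 - fp
  dplyr::bind_cols(
    tibble::tibble(cutoff = thr[best], youden = unname(J[best]),
                   tp = tp, fp = fp, tn = tn, fn = fn),
    .confusion_metrics(tp, fp, tn, fn))
}

#' Univariate AUC per feature
#'
#' Rank AUC of each feature against the label, oriented so every reported
#' AUC is >= 0.5 (the direction of each feature is not fixed a priori).
#'
#' @param data Tibble of numeric features.
#' @param labels "high"/"low" labels.
#' @return Tibble: `feature`, `auc`, `direction` (+1 if higher values
#'   indicate "high").
#' @export
per_feature_auc <- function(data, labels) {
  feats <- data[vapply(data, is.numeric, logical(1))]
  feats <- feats[setdiff(names(feats), "subject_id")]
  purrr::map_dfr(names(feats), function(nm) {
    a <- roc_auc(feats[[nm]], labels)$auc
    tibble::tibble(feature = nm,
                   auc = max(a, 1 - a),
                   direction = if (a >= 0.5) 1 else -1)
  })
}

# deterministic stratified fold assignment
.stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the SVM panel
#'
#' Splits subjects into stratified folds from the seed, refits the
#' standardization and SVM on each training split (optionally re-running
#' feature selection inside the fold for a leakage-free protocol), scores
#' the held-out subjects and reports per-fold AUCs. Folds are reduced
#' with a warning when a class is too small for the requested count.
#'
#' @param data Feature tibble (panel columns, or all features when
#'   `refit_selection`).
#' @param labels "high"/"low" labels.
#' @param folds Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param refit_selection If `TRUE`, re-run [select_panel()] within each
#'   training fold (leakage-free mode); the default `FALSE` evaluates a
#'   fixed panel, mirroring selection on the full cohort.
#' @param k Panel size when `refit_selection`.
#' @param ... Passed to [fit_ki67_svm()].
#' @return List: `fold_auc` (numeric), `mean_auc`, `sd_auc`, `scores`
#'   (out-of-fold score per subject), `fold` assignment.
#' @export
crossvalidate_svm <- function(data, labels, folds = 10, seed = 1,
                              refit_selection = FALSE, k = 5, ...) {
  n_min <- min(table(labels))
  if (folds > n_min) {
    warning("reducing folds to the smallest class size (", n_min, ")")
    folds <- n_min
  }
  fold <- .stratified_folds(labels, folds, seed)
  scores <- numeric(length(labels))
  fold_auc <- rep(NA_real_, folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- fold == f
    if (length(unique(labels[tr])) < 2) {
      warning("fold ", f, " skipped: single-class training split")
      next
    }
    dtr <- data[tr, , drop = FALSE]
    panel <- names(dtr)[vapply(dtr, is.numeric, logical(1))]
    if (refit_selection) {
      sel <- select_panel(dplyr::mutate(dtr, label = labels[tr]),
                          screen = NULL, k = k)
      panel <- sel$panel
    }
    fit <- fit_ki67_svm(dtr[panel], labels[tr], seed = seed + f, ...)
    sc <- predict(fit, data[te, panel, drop = FALSE])
    scores[te] <- sc
    if (length(unique(labels[te])) == 2)
      fold_auc[f] <- roc_auc(sc, labels[te])$auc
  }
  ok <- !is.na(fold_auc)
  list(fold_auc = fold_auc, mean_auc = mean(fold_auc[ok]),
       sd_auc = sd(fold_auc[ok]), scores = scores, fold = fold)
}

#' Evaluate a feature panel as the paper-style model report
#'
#' Fits the SVM on the full cohort, reports apparent ROC AUC with its
#' DeLong interval, the Youden operating point with its five metrics,
#' univariate per-feature AUCs, and stratified 10-fold cross-validation.
#'
#' @param data Feature tibble containing the panel columns.
#' @param labels "high"/"low" labels.
#' @param panel Character vector of panel feature names.
#' @param folds CV folds.
#' @param seed Seed for the SVM calibration and fold assignment.
#' @param ... Passed to [fit_ki67_svm()].
#' @return A `ki67_eval` object (list): `roc`, `youden`, `cv`,
#'   `per_feature`, `scores`, `labels`, `panel`.
#' @export
evaluate_panel <- function(data, labels, panel, folds = 10, seed = 1, ...) {
  fit <- fit_ki67_svm(data[panel], labels, seed = seed, ...)
  scores <- predict(fit, data[panel])
  structure(list(
    roc = roc_auc(scores, labels),
    youden = youden_metrics(scores, labels),
    cv = crossvalidate_svm(data[panel], labels, folds = folds, seed = seed,
                           ...),
    per_feature = per_feature_auc(data[panel], labels),
    scores = scores, labels = labels, panel = panel, fit = fit),
    class = "ki67_eval")
}

#' @export
print.ki67_eval <- function(x, ...) {
  cat("Ki-67 SVM evaluation (", length(x$labels), " subjects, ",
      length(x$panel), "-feature panel)\n", sep = "")
  cat(sprintf("  AUC %.3f [%.3f, %.3f]\n", x$roc$auc, x$roc$ci_lower,
              x$roc$ci_upper))
  cat(sprintf("  Youden cutoff %.3f: acc %.3f sens %.3f spec %.3f ppv %.3f npv %.3f\n",
              x$youden$cutoff, x$youden$accuracy, x$youden$sensitivity,
              x$youden$specificity, x$youden$ppv, x$youden$npv))
  cat(sprintf("  CV AUC %.3f +/- %.3f over %d folds\n", x$cv$mean_auc,
              x$cv$sd_auc, length(x$cv$fold_auc)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-metric summary of a model evaluation
#'
#' @param x A `ki67_eval`.
#' @param ... Unused.
#' @return Tibble with `metric`, `estimate` rows.
#' @export
tidy.ki67_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("auc", "auc_ci_lower", "auc_ci_upper", "cutoff", "accuracy",
               "sensitivity", "specificity", "ppv", "npv", "cv_auc_mean",
               "cv_auc_sd"),
    estimate = c(x$roc$auc, x$roc$ci_lower, x$roc$ci_upper,
                 x$youden$cutoff, x$youden$accuracy, x$youden$sensitivity,
                 x$youden$specificity, x$youden$ppv, x$youden$npv,
                 x$cv$mean_auc, x$cv$sd_auc))
}

#' One-row summary of a model evaluation
#'
#' @param x A `ki67_eval`.
#' @param ... Unused.
#' @return One-row tibble of the headline metrics.
#' @export
glance.ki67_eval <- function(x, ...) {
  tibble::tibble(n = length(x$labels), n_features = length(x$panel),
                 auc = x$roc$auc, ci_lower = x$roc$ci_lower,
                 ci_upper = x$roc$ci_upper, cutoff = x$youden$cutoff,
                 accuracy = x$youden$accuracy,
                 sensitivity = x$youden$sensitivity,
                 specificity = x$youden$specificity,
                 cv_auc_mean = x$cv$mean_auc, cv_auc_sd = x$cv$sd_auc)
}
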