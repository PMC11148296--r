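test_that("rank AUC matches oracles, reversal and monotone invariance", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3),
                       c("high", "high", "low", "low"))$auc, 1)
  set.seed(29)
  for (i in 1:10) {
    sc <- round(rnorm(30), 1)                # ties likely
    lab <- sample(c("high", "low"), 30, replace = TRUE,
                  prob = c(0.6, 0.4))
    if (length(unique(lab)) < 2) next
    a <- roc_auc(sc, lab)$auc
    expect_equal(a, oracle_auc(sc, lab), tolerance = 1e-12)
    expect_equal(roc_auc(-sc, lab)$auc, 1 - a, tolerance = 1e-12)
    expect_equal(roc_auc(exp(sc), lab)$auc, a, tolerance = 1e-12)
  }
  expect_warning(r <- roc_auc(rep(1, 10), rep(c("high", "low"), 5)),
                 "constant")
  expect_equal(r$auc, 0.5)
})

test_that("AUC and DeLong interval agree with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(30)
  sc <- rnorm(60)
  lab <- rep(c("high", "low"), times = c(35, 25))
  sc[lab == "high"] <- sc[lab == "high"] + 0.8
  mine <- roc_auc(sc, lab)
  ref <- pROC::roc(response = lab, predictor = sc, levels = c("low", "high"),
                   direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(mine$ci_lower, ci[1], tolerance = 0.02)
  expect_equal(mine$ci_upper, ci[3], tolerance = 0.02)
})

test_that("the Youden cutoff maximizes J and reports coherent metrics", {
  # perfectly separated scores
  y <- youden_metrics(c(1, 2, 3, 10, 11, 12),
                      c(rep("low", 3), rep("high", 3)))
  expect_equal(y$youden, 1)
  expect_true(all(unlist(y[c("accuracy", "sensitivity", "specificity",
                             "ppv", "npv")]) == 1))
  # constant scores degenerate to prevalence
  lab <- rep(c("high", "low"), times = c(6, 4))
  yc <- youden_metrics(rep(2, 10), lab)
  expect_equal(yc$youden, 0)
  expect_equal(yc$accuracy, 0.6)

  # brute-force threshold scan agrees on random instances
  set.seed(31)
  for (i in 1:10) {
    sc <- round(runif(40), 2)
    lab <- sample(c("high", "low"), 40, replace = TRUE)
    if (length(unique(lab)) < 2) next
    y <- youden_metrics(sc, lab)
    jmax <- max(vapply(unique(sc), function(t) {
      sens <- mean(sc[lab == "high"] >= t)
      spec <- mean(sc[lab == "low"] < t)
      sens + spec - 1
    }, numeric(1)))
    expect_equal(y$youden, jmax, tolerance = 1e-12)
    cm <- confusion_metrics(y$tp, y$fp, y$tn, y$fn)
    expect_equal(y$accuracy, cm$accuracy)
  }
})

test_that("the 81/38 confusion matrix maps to the five reference metrics", {
  m <- confusion_metrics(tp = 65, fp = 12, tn = 26, fn = 16)
  expect_equal(round(m$accuracy, 3), 0.765)
  expect_equal(round(m$sensitivity, 3), 0.802)
  expect_equal(round(m$specificity, 3), 0.684)
  expect_equal(round(m$ppv, 3), 0.844)
  expect_equal(round(m$npv, 3), 0.619)
})

test_that("per-feature AUC is the oriented rank statistic", {
  set.seed(32)
  lab <- rep(c("high", "low"), times = c(30, 20))
  df <- tibble::tibble(copy = as.numeric(lab == "high"),
                       noise = rnorm(50), inv = -as.numeric(lab == "high"))
  pf <- per_feature_auc(df, lab)
  expect_equal(pf$auc[pf$feature == "copy"], 1)
  expect_equal(pf$auc[pf$feature == "inv"], 1)
  expect_equal(pf$direction[pf$feature == "inv"], -1)
  # identity with the Mann-Whitney U statistic
  x <- rnorm(50)
  u <- suppressWarnings(wilcox.test(x[lab == "high"],
                                    x[lab == "low"])$statistic)
  expect_equal(roc_auc(x, lab)$auc, unname(u) / (30 * 20),
               tolerance = 1e-12)
})

test_that("the SVM separates a separable toy and is seed-deterministic", {
  df <- tibble::tibble(f = c(-2, -1.5, -1.2, 1.1, 1.6, 2, -1.8, 1.4))
  lab <- c(rep("low", 3), rep("high", 3), "low", "high")
  fit <- fit_ki67_svm(df, lab, seed = 1)
  sc <- predict(fit, df)
  expect_equal(roc_auc(sc, lab)$auc, 1)
  fit2 <- fit_ki67_svm(df, lab, seed = 1)
  expect_equal(sc, predict(fit2, df), tolerance = 1e-12)
  expect_error(fit_ki67_svm(df, rep("high", 8)), "both classes")
})

test_that("a duplicated feature column leaves the RBF model unchanged", {
  # gamma = 1/d keeps gamma * squared-distance invariant under duplication
  set.seed(33)
  df <- tibble::tibble(f = rnorm(40))
  lab <- ifelse(df$f + rnorm(40, sd = 0.5) > 0, "high", "low")
  if (length(unique(lab)) < 2) lab[1:2] <- c("high", "low")
  s1 <- predict(fit_ki67_svm(df, lab, seed = 2), df)
  df2 <- tibble::tibble(f = df$f, g = df$f)
  s2 <- predict(fit_ki67_svm(df2, lab, seed = 2), df2)
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("cross-validation is stratified, deterministic and calibrated", {
  set.seed(34)
  n <- 80
  lab <- rep(c("high", "low"), times = c(50, 30))
  df <- tibble::tibble(s = as.numeric(lab == "high") + rnorm(n, sd = 0.7),
                       z = rnorm(n))
  cv <- crossvalidate_svm(df, lab, folds = 10, seed = 5)
  expect_length(cv$fold_auc, 10)
  expect_true(all(table(cv$fold, lab)[, "low"] == 3))
  cv2 <- crossvalidate_svm(df, lab, folds = 10, seed = 5)
  expect_identical(cv$fold_auc, cv2$fold_auc)
  expect_gt(cv$mean_auc, 0.6)               # real signal

  # shuffled labels sit in the permutation null band
  perm <- sample(lab)
  cvp <- crossvalidate_svm(df, perm, folds = 10, seed = 5)
  expect_lt(abs(cvp$mean_auc - 0.5), 0.25)

  sub <- c(1:8, 51:56)                      # 8 high, 6 low
  expect_warning(crossvalidate_svm(df[sub, ], lab[sub], folds = 10,
                                   seed = 1),
                 "reducing folds")
})

test_that("panel evaluation bundles ROC, Youden, CV and tidies", {
  set.seed(35)
  n <- 60
  lab <- rep(c("high", "low"), times = c(40, 20))
  df <- tibble::tibble(a = as.numeric(lab == "high") + rnorm(n, sd = 0.8),
                       b = rnorm(n))
  ev <- evaluate_panel(df, lab, panel = c("a", "b"), folds = 5, seed = 3)
  expect_s3_class(ev, "ki67_eval")
  expect_true(ev$roc$ci_lower <= ev$roc$auc && ev$roc$auc <= ev$roc$ci_upper)
  td <- generics::tidy(ev)
  expect_identical(td$metric[1], "auc")
  gl <- generics::glance(ev)
  expect_equal(gl$n, n)
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
  pts <- roc_points(ev)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
})
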