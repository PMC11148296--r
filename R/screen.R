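#' Normality-gated two-group comparison of one feature
#'
#' Uses the pooled two-sample t-test when both groups pass a Shapiro-Wilk
#' normality test at `alpha_normality`, and the Mann-Whitney U test
#' otherwise (two-sided in either case). A feature constant in both
#' groups yields p = 1 with a warning.
#'
#' @param high,low Numeric samples for the two cohorts (each n >= 3).
#' @param alpha_normality Significance level of the normality gate.
#' @return One-row tibble: `test`, `p_value`.
#' @export
compare_feature <- function(high, low, alpha_normality = 0.05) {
  stopifnot(length(high) >= 3, length(low) >= 3)
  if (sd(high) == 0 && sd(low) == 0 && high[1] == low[1]) {
    warning("feature constant in both groups; p = 1")
    return(tibble::tibble(test = "none", p_value = 1))
  }
  normal <- function(x) {
    if (sd(x) == 0 || length(x) < 3 || length(x) > 5000) return(FALSE)
    shapiro.test(x)$p.value > alpha_normality
  }
  if (normal(high) && normal(low)) {
    p <- t.test(high, low, var.equal = TRUE)$p.value
    tibble::tibble(test = "t", p_value = p)
  } else {
    p <- suppressWarnings(wilcox.test(high, low, exact = FALSE)$p.value)
    tibble::tibble(test = "mann-whitney", p_value = p)
  }
}

#' Screen all features between Ki-67 cohorts
#'
#' Applies [compare_feature()] to every feature column and returns the
#' per-feature test results with Manhattan-plot coordinates. P-values are
#' unadjusted by default; the significance call is `p < alpha`.
#'
#' @param data Tibble with a label column and numeric feature columns
#'   (non-feature columns such as `subject_id` are ignored).
#' @param label_col Name of the label column (values "high"/"low").
#' @param alpha Significance level (default 0.05).
#' @param alpha_normality Normality-gate level.
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   ("none" by default, mirroring an unadjusted raw-p screen).
#' @return A `ki67_screen` tibble: `feature`, `test`, `p_value`,
#'   `neg_log10_p`, `significant`; attribute `alpha`.
#' @export
screen_features <- function(data, label_col = "label", alpha = 0.05,
                            alpha_normality = 0.05, adjust = "none") {
  labels <- data[[label_col]]
  if (length(unique(labels)) < 2)
    stop("invalid cohort: both labels must be present")
  feats <- data[setdiff(names(data), c(label_col, "subject_id"))]
  feats <- feats[vapply(feats, is.numeric, logical(1))]
  res <- purrr::map_dfr(names(feats), function(nm) {
    x <- feats[[nm]]
    r <- suppressWarnings(
      compare_feature(x[labels == "high"], x[labels == "low"],
                      alpha_normality = alpha_normality))
    dplyr::mutate(r, feature = nm, .before = 1)
  })
  res$p_value <- stats::p.adjust(res$p_value, method = adjust)
  res <- dplyr::mutate(res,
    neg_log10_p = -log10(p_value),
    significant = p_value < alpha)
  attr(res, "alpha") <- alpha
  class(res) <- c("ki67_screen", class(res))
  res
}

#' Pooled mean and standard deviation from group summaries
#'
#' Combines per-group (n, mean, SD) summaries into the mean and SD of the
#' concatenated sample, via the within- plus between-group sum-of-squares
#' identity with denominator (sum n) - 1. Exact: equals direct
#' computation on the pooled raw data.
#'
#' @param n,mean,sd Equal-length numeric vectors of group summaries.
#' @return One-row tibble: `n`, `mean`, `sd`.
#' @export
pooled_mean_sd <- function(n, mean, sd) {
  stopifnot(length(n) == length(mean), length(n) == length(sd), any(n >= 2))
  N <- sum(n)
  m <- sum(n * mean) / N
  ss <- sum((n - 1) * sd^2) + sum(n * (mean - m)^2)
  tibble::tibble(n = N, mean = m, sd = sqrt(ss / (N - 1)))
}

#' Chi-square test of a contingency table
#'
#' Two-sided chi-square p-value with Yates continuity correction for 2x2
#' tables and the plain chi-square for larger tables.
#'
#' @param counts Matrix of nonnegative counts (r x c, r,c >= 2).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
categorical_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("undefined test: contingency table has a zero marginal")
  correct <- all(dim(counts) == c(2, 2))
  ct <- suppressWarnings(chisq.test(counts, correct = correct))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Pooled-variance t-test from group summaries
#'
#' Two-sample t-test computed from printed (n, mean, SD) summaries with
#' the pooled variance and df = n1 + n2 - 2.
#'
#' @param n1,mean1,sd1 First group's summary.
#' @param n2,mean2,sd2 Second group's summary.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
summary_t_test <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}
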