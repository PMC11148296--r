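#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan plot of a feature screen
#'
#' One point per feature at -log10(p), colored by feature family prefix,
#' with the significance line at -log10(alpha).
#'
#' @param object A `ki67_screen` from [screen_features()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ki67_screen <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- tibble::as_tibble(object)
  df$index <- seq_len(nrow(df))
  df$family <- sub("^(original|log_sigma[^_]*(_[0-9]+)*_mm_3D|wavelet_[LH]{3})_([a-z]+)_.*$",
                   "\\3", df$feature)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$neg_log10_p,
                                   color = .data$family)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), color = "blue",
                        linetype = "dashed") +
    ggplot2::labs(x = "feature index", y = expression(-log[10](p)),
                  color = "family") +
    ggplot2::theme_minimal()
}

#' ROC points of an evaluation
#'
#' @param eval A `ki67_eval`.
#' @return Tibble of (fpr, tpr) pairs along the score thresholds.
#' @export
roc_points <- function(eval) {
  stopifnot(inherits(eval, "ki67_eval"))
  thr <- c(Inf, sort(unique(eval$scores), decreasing = TRUE))
  n1 <- sum(eval$labels == "high"); n0 <- sum(eval$labels == "low")
  purrr::map_dfr(thr, function(t) {
    pred <- eval$scores >= t
    tibble::tibble(
      threshold = t,
      fpr = sum(pred & eval$labels == "low") / n0,
      tpr = sum(pred & eval$labels == "high") / n1)
  })
}

#' ROC curve of a model evaluation
#'
#' @param object A `ki67_eval`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the AUC annotated.
#' @export
autoplot.ki67_eval <- function(object, ...) {
  pts <- roc_points(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey70",
                         linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUC %.2f [%.2f, %.2f]",
                                      object$roc$auc, object$roc$ci_lower,
                                      object$roc$ci_upper)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}
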