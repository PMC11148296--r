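#' First-order (histogram) features of a masked intensity sample
#'
#' The 18 standard first-order descriptors. Moments use the population
#' convention (denominator n); kurtosis is Pearson (a normal sample is
#' near 3); the skewness and kurtosis of a constant sample are 0 by
#' convention. Entropy and Uniformity are computed on the fixed-bin-width
#' histogram ([discretize_fixed_binwidth()]), with entropy in bits.
#'
#' @param values Numeric vector of at least 2 voxel intensities.
#' @param bin_width Gray-level bin width for Entropy/Uniformity.
#' @param voxel_volume Physical voxel volume in mm^3 (for TotalEnergy).
#' @return Named numeric vector of 18 features.
#' @export
firstorder_features <- function(values, bin_width = 5, voxel_volume = 1) {
  stopifnot(length(values) >= 2)
  n <- length(values)
  mu <- mean(values)
  v <- mean((values - mu)^2)
  s <- sqrt(v)
  skew <- if (s > 0) mean((values - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((values - mu)^4) / v^2 else 0
  bins <- discretize_fixed_binwidth(values, bin_width)
  p <- tabulate(bins) / n
  p <- p[p > 0]
  q <- quantile(values, c(0.1, 0.25, 0.75, 0.9), names = FALSE, type = 7)
  robust <- values[values >= q[1] & values <= q[4]]
  c(
    Mean = mu,
    Median = median(values),
    Minimum = min(values),
    Maximum = max(values),
    Range = max(values) - min(values),
    Variance = v,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2),
    RootMeanSquared = sqrt(mean(values^2)),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    InterquartileRange = q[3] - q[2])
}
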