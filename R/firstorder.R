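first_order_names <- c(
  "Mean", "Median", "Minimum", "Maximum", "Range", "Variance",
  "StandardDeviation", "Skewness", "Kurtosis", "Energy", "Entropy",
  "Uniformity", "MeanAbsoluteDeviation", "RootMeanSquare")

#' First-order intensity features
#'
#' Fourteen distribution summaries of the masked voxel intensities.
#' Moments are population moments; skewness is `m3 / m2^(3/2)` and kurtosis
#' the (non-excess) `m4 / m2^2`, both defined as 0 for a constant input.
#' Entropy (bits) and uniformity are computed on the equal-width
#' discretized histogram with `0 log 0 = 0`, so a constant region has
#' entropy 0 and uniformity 1.
#'
#' @param values numeric vector of masked intensities.
#' @param n_bins gray levels for the entropy/uniformity histogram.
#' @return Named numeric vector of 14 features.
#' @examples
#' first_order_features(c(1, 2, 3, 4))[c("Mean", "Range")]
#' @export
first_order_features <- function(values, n_bins = 32) {
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 else 0
  p <- tabulate(discretize(values, n_bins), nbins = n_bins) / n
  nz <- p[p > 0]
  c(setNames(
    c(mu, median(values), min(values), max(values), diff(range(values)),
      m2, sqrt(m2), skew, kurt, sum(values^2), -sum(nz * log2(nz)),
      sum(p^2), mean(abs(values - mu)), sqrt(mean(values^2))),
    first_order_names))
}
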