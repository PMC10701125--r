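glcm_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Energy", "Entropy", "InverseDifference",
  "InverseDifferenceMoment", "IMC1", "IMC2", "InverseDifferenceNormalized",
  "InverseDifferenceMomentNormalized", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumVariance")

# the four in-plane offsets (rows, cols) at unit distance: 0, 45, 90, 135 deg
texture_offsets <- function(distance = 1) {
  list(c(0L, 1L), c(-1L, 1L), c(1L, 0L), c(1L, 1L)) |>
    lapply(function(o) o * as.integer(distance))
}

log2z <- function(x) ifelse(x > 0, log2(x), 0)

# 22 Haralick-style features from one normalized symmetric GLCM
glcm_feature_values <- function(p) {
  ng <- nrow(p)
  iv <- seq_len(ng)
  i <- matrix(iv, ng, ng); j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sx <- sqrt(sum((iv - mux)^2 * px)); sy <- sqrt(sum((iv - muy)^2 * py))
  corr <- if (sx > 0 && sy > 0)
    sum(p * (i - mux) * (j - muy)) / (sx * sy) else 1
  psum <- as.vector(rowsum(as.vector(p), as.vector(i + j)))   # k = 2..2ng
  ksum <- sort(unique(as.vector(i + j)))
  pdiff <- as.vector(rowsum(as.vector(p), as.vector(abs(i - j))))
  kdiff <- sort(unique(as.vector(abs(i - j))))                # 0..ng-1
  da <- sum(kdiff * pdiff)
  sa <- sum(ksum * psum)
  hxy <- -sum(p * log2z(p))
  pxy <- outer(px, py)
  hxy1 <- -sum(p * log2z(pxy))
  hxy2 <- -sum(pxy * log2z(pxy))
  hx <- -sum(px * log2z(px)); hy <- -sum(py * log2z(py))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  offdiag <- i != j
  setNames(c(
    sum(i * j * p),
    sum((i + j - mux - muy)^4 * p),
    sum((i + j - mux - muy)^3 * p),
    sum((i + j - mux - muy)^2 * p),
    sum((i - j)^2 * p),
    corr,
    da,
    -sum(pdiff * log2z(pdiff)),
    sum((kdiff - da)^2 * pdiff),
    sum(p^2),
    hxy,
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + (i - j)^2)),
    imc1,
    imc2,
    sum(p / (1 + abs(i - j) / ng)),
    sum(p / (1 + (i - j)^2 / ng^2)),
    sum(p[offdiag] / (i[offdiag] - j[offdiag])^2),
    max(p),
    sa,
    -sum(psum * log2z(psum)),
    sum((ksum - sa)^2 * psum)
  ), glcm_names)
}

#' Grey-level co-occurrence matrix features
#'
#' Builds, per slice and per in-plane direction (0, 45, 90, 135 degrees) at
#' the given distance, the symmetric normalized GLCM from voxel pairs that
#' both lie inside the mask, computes 22 Haralick-style features from each
#' matrix, and averages over directions and slices. On a constant region
#' (all probability mass at one level) correlation is 1 by convention and
#' IMC1 is 0; all logarithms are base 2 with `0 log 0 = 0`.
#'
#' @param levels integer array (2-D or 3-D) of gray levels `1..n_bins`, with
#'   0 marking voxels outside the mask.
#' @param n_bins number of gray levels.
#' @param distance pair offset in voxels.
#' @return Named numeric vector of 22 features.
#' @examples
#' lev <- matrix(c(1L, 1L, 2L, 2L), 2)  # two vertical stripes
#' glcm_features(lev, n_bins = 2)["Contrast"]
#' @export
glcm_features <- function(levels, n_bins = max(levels), distance = 1) {
  if (is.matrix(levels)) levels <- array(levels, c(dim(levels), 1L))
  offsets <- texture_offsets(distance)
  acc <- NULL; nmat <- 0L
  for (s in seq_len(dim(levels)[3])) {
    sl <- array(levels[, , s], dim(levels)[1:2])
    storage.mode(sl) <- "integer"
    for (off in offsets) {
      counts <- cpp_glcm_counts(sl, as.integer(n_bins), off[1], off[2])
      tot <- sum(counts)
      if (tot == 0) next
      f <- glcm_feature_values(counts / tot)
      acc <- if (is.null(acc)) f else acc + f
      nmat <- nmat + 1L
    }
  }
  if (nmat == 0L)
    stop("texture undefined: no valid in-mask voxel pairs", call. = FALSE)
  acc / nmat
}

#' Features of a single co-occurrence matrix
#'
#' Computes the 22-feature set from one normalized symmetric GLCM (no
#' direction/slice averaging), e.g. a matrix from [glcm_matrix()].
#'
#' @param p normalized symmetric co-occurrence matrix (sums to 1).
#' @return Named numeric vector of 22 features.
#' @export
glcm_matrix_features <- function(p) {
  if (abs(sum(p) - 1) > 1e-8)
    stop("`p` must be normalized (sum to 1)", call. = FALSE)
  glcm_feature_values(p)
}

#' Construct one normalized symmetric GLCM
#'
#' Exposed for inspection and testing; [glcm_features()] uses the same
#' accumulation internally.
#'
#' @inheritParams glcm_features
#' @param offset integer `c(rows, cols)` displacement.
#' @return `n_bins` x `n_bins` matrix summing to 1 (all-zero if no pairs).
#' @export
glcm_matrix <- function(levels, n_bins = max(levels), offset = c(0L, 1L)) {
  if (is.matrix(levels)) levels <- array(levels, c(dim(levels), 1L))
  counts <- matrix(0, n_bins, n_bins)
  for (s in seq_len(dim(levels)[3])) {
    sl <- array(levels[, , s], dim(levels)[1:2])
    storage.mode(sl) <- "integer"
    counts <- counts + cpp_glcm_counts(sl, as.integer(n_bins),
                                       as.integer(offset[1]),
                                       as.integer(offset[2]))
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}
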