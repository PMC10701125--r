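glrlm_names <- c("SRE", "LRE", "GLN", "RLN", "RP",
                 "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE")

# 11 features from one run-length count matrix r (levels x lengths)
glrlm_feature_values <- function(r, n_voxels) {
  nr <- sum(r)
  iv <- seq_len(nrow(r)); jv <- seq_len(ncol(r))
  i2 <- matrix(iv^2, nrow(r), ncol(r))
  j2 <- matrix(jv^2, nrow(r), ncol(r), byrow = TRUE)
  setNames(c(
    sum(r / j2) / nr,
    sum(r * j2) / nr,
    sum(rowSums(r)^2) / nr,
    sum(colSums(r)^2) / nr,
    nr / n_voxels,
    sum(r / i2) / nr,
    sum(r * i2) / nr,
    sum(r / (i2 * j2)) / nr,
    sum(r * i2 / j2) / nr,
    sum(r * j2 / i2) / nr,
    sum(r * i2 * j2) / nr
  ), glrlm_names)
}

#' Grey-level run-length matrix features
#'
#' Counts, per slice and per in-plane direction, the maximal runs of equal
#' gray level inside the mask, and computes 11 run-emphasis features (short/
#' long run emphasis, gray-level and run-length non-uniformity, run
#' percentage, low/high gray-level emphases and their joint variants, e.g.
#' `SRE = (1/N_r) sum r(i,j)/j^2`, `SRLGE = (1/N_r) sum r(i,j)/(i^2 j^2)`).
#' Features are averaged over directions and slices.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 11 features.
#' @examples
#' glrlm_features(matrix(c(1L, 1L, 2L), 1), n_bins = 2)[c("SRE", "SRLGE")]
#' @export
glrlm_features <- function(levels, n_bins = max(levels)) {
  if (is.matrix(levels)) levels <- array(levels, c(dim(levels), 1L))
  if (sum(levels > 0) == 0) stop("empty mask", call. = FALSE)
  offsets <- texture_offsets(1)
  acc <- NULL; nmat <- 0L
  for (s in seq_len(dim(levels)[3])) {
    sl <- array(levels[, , s], dim(levels)[1:2])
    storage.mode(sl) <- "integer"
    nvox <- sum(sl > 0)
    if (nvox == 0) next
    for (off in offsets) {
      counts <- cpp_glrlm_counts(sl, as.integer(n_bins), off[1], off[2])
      f <- glrlm_feature_values(counts, nvox)
      acc <- if (is.null(acc)) f else acc + f
      nmat <- nmat + 1L
    }
  }
  acc / nmat
}

#' Features of a single run-length matrix
#'
#' Computes the 11-feature set from one run-length count matrix (no
#' direction/slice averaging), e.g. a matrix from [glrlm_matrix()].
#'
#' @param r run-length count matrix (levels x run lengths).
#' @param n_voxels number of in-mask voxels (for run percentage).
#' @return Named numeric vector of 11 features.
#' @export
glrlm_matrix_features <- function(r, n_voxels) {
  if (sum(r) == 0) stop("no runs in `r`", call. = FALSE)
  glrlm_feature_values(r, n_voxels)
}

#' Construct one run-length count matrix
#'
#' @inheritParams glcm_matrix
#' @return levels x max-run-length matrix of run counts for one slice stack
#'   and one direction.
#' @export
glrlm_matrix <- function(levels, n_bins = max(levels), offset = c(0L, 1L)) {
  if (is.matrix(levels)) levels <- array(levels, c(dim(levels), 1L))
  acc <- NULL
  for (s in seq_len(dim(levels)[3])) {
    sl <- array(levels[, , s], dim(levels)[1:2])
    storage.mode(sl) <- "integer"
    counts <- cpp_glrlm_counts(sl, as.integer(n_bins),
                               as.integer(offset[1]), as.integer(offset[2]))
    acc <- if (is.null(acc)) counts else acc + counts
  }
  acc
}
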