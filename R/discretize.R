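#' Discretize intensities to gray levels
#'
#' Equal-width binning over the observed range of the (masked) values:
#' `level = 1 + floor(n_bins * (x - min) / (max - min))`, with the maximum
#' clamped to `n_bins`. A constant input maps everything to level 1. A fixed
#' bin *count* (rather than fixed bin width) keeps texture-matrix size
#' bounded across channels with very different dynamic ranges.
#'
#' @param values numeric vector of intensities (e.g. masked HU values).
#' @param n_bins number of gray levels, >= 2.
#' @return Integer vector of levels in `1..n_bins`.
#' @examples
#' discretize(0:31, 32)
#' @export
discretize <- function(values, n_bins = 32) {
  if (length(values) == 0) stop("`values` must be non-empty", call. = FALSE)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  lev <- 1L + as.integer(floor(n_bins * (values - rng[1]) / diff(rng)))
  pmin(lev, as.integer(n_bins))
}

# Level-coded slab: 0 outside the mask, 1..n_bins inside, binned over the
# pooled in-mask range of all slices so levels are comparable across slices.
level_code <- function(channel, mask_vox, n_bins) {
  lev <- array(0L, dim(channel))
  inside <- mask_vox == 1L
  lev[inside] <- discretize(channel[inside], n_bins)
  lev
}
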