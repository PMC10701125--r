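#' Segment skeletal muscle by Hounsfield-unit window
#'
#' Keeps a voxel iff it lies inside the region of interest *and* its HU value
#' falls inside `[low, high]` (both bounds inclusive, the standard
#' body-composition convention). The default window -29..+150 HU is the
#' established skeletal-muscle range.
#'
#' @param slab a [ct_slab()].
#' @param roi a [muscle_mask()] congruent with `slab`, the contoured region
#'   of interest.
#' @param low,high HU window bounds, `low <= high`.
#' @return A [muscle_mask()] with the window recorded in `provenance`.
#' @examples
#' slab <- ct_slab(array(c(-1000, -30, -29, 0, 150, 151, 0, 0),
#'                       c(2, 2, 2)), 1)
#' roi <- muscle_mask(array(1L, c(2, 2, 2)))
#' sum(apply_hu_threshold(slab, roi)$voxels)
#' @export
apply_hu_threshold <- function(slab, roi, low = -29, high = 150) {
  check_congruent(slab, roi)
  if (low > high) stop("`low` must not exceed `high`", call. = FALSE)
  keep <- roi$voxels == 1L & slab$voxels >= low & slab$voxels <= high
  out <- array(0L, dim(roi$voxels))
  out[keep] <- 1L
  muscle_mask(out, provenance = list(hu_window = c(low = low, high = high)))
}

#' Cross-sectional muscle area per slice
#'
#' Converts voxel counts to physical area: `count * spacing^2 / 100` cm2 per
#' slice; the scalar summary is the unweighted mean over slices, which damps
#' single-slice variation in muscle distribution.
#'
#' @param mask a [muscle_mask()].
#' @param spacing in-plane pixel spacing in mm.
#' @return A list with `per_slice` (cm2, one per slice) and `mean_area` (cm2).
#' @examples
#' m <- muscle_mask(array(rep(c(1L, 0L), c(100, 156)), c(16, 16, 1)))
#' cross_sectional_area(m, spacing = 1)$mean_area  # 1 cm2
#' @export
cross_sectional_area <- function(mask, spacing) {
  if (spacing <= 0) stop("`spacing` must be positive", call. = FALSE)
  counts <- apply(mask$voxels, 3, sum)
  if (all(counts == 0))
    stop("empty segmentation: no muscle voxels on any slice", call. = FALSE)
  per_slice <- counts * spacing^2 / 100
  list(per_slice = per_slice, mean_area = mean(per_slice))
}

#' Skeletal muscle index
#'
#' SMI = cross-sectional muscle area (cm2) normalized by height squared (m2),
#' the standard surrogate for whole-body muscle mass.
#'
#' @param area muscle area in cm2.
#' @param height patient height in m.
#' @return SMI in cm2/m2.
#' @examples
#' compute_smi(140, 1.70)
#' @export
compute_smi <- function(area, height) {
  if (any(area <= 0)) stop("`area` must be positive", call. = FALSE)
  if (any(height <= 0)) stop("`height` must be positive (m)", call. = FALSE)
  area / height^2
}

#' Segment a slab and compute its SMI in one step
#'
#' @inheritParams apply_hu_threshold
#' @param height patient height in m.
#' @return List: `mask`, `area` (cm2, mean over slices), `smi` (cm2/m2).
#' @export
segment_smi <- function(slab, roi, height, low = -29, high = 150) {
  mask <- apply_hu_threshold(slab, roi, low, high)
  area <- cross_sectional_area(mask, slab$pixel_spacing)
  list(mask = mask, area = area$mean_area,
       smi = compute_smi(area$mean_area, height))
}
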