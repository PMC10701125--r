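#' CT slab and muscle mask containers
#'
#' A `ct_slab` holds a small stack of axial CT slices (HU values) together
#' with its voxel geometry; a `muscle_mask` is a congruent binary array
#' marking muscle voxels (either a contoured region of interest or the
#' result of HU thresholding). Arrays are indexed `[row, col, slice]`.
#'
#' @param voxels numeric 3-D array of Hounsfield units (rows x cols x slices).
#'   A matrix is promoted to a single-slice array.
#' @param pixel_spacing in-plane voxel edge length in mm.
#' @param slice_thickness slice thickness in mm.
#' @return An object of class `ct_slab`.
#' @examples
#' slab <- ct_slab(array(0, c(8, 8, 5)), pixel_spacing = 0.88)
#' dim(slab$voxels)
#' @export
ct_slab <- function(voxels, pixel_spacing, slice_thickness = 5) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array (rows x cols x slices)", call. = FALSE)
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      pixel_spacing <= 0)
    stop("`pixel_spacing` must be a single positive number (mm)", call. = FALSE)
  if (slice_thickness <= 0)
    stop("`slice_thickness` must be positive (mm)", call. = FALSE)
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3000)
    warning("HU values outside the plausible range [-1024, 3000]")
  structure(
    list(voxels = voxels, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness),
    class = "ct_slab"
  )
}

#' @param provenance optional list describing how the mask was made
#'   (e.g. threshold bounds).
#' @rdname ct_slab
#' @export
muscle_mask <- function(voxels, provenance = NULL) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask `voxels` must be a 3-D array", call. = FALSE)
  v <- as.numeric(voxels)
  if (!all(v %in% c(0, 1)))
    stop("mask voxels must be 0/1", call. = FALSE)
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, provenance = provenance),
            class = "muscle_mask")
}

#' @export
print.ct_slab <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_slab> %d x %d x %d slices, %.2f mm pixels, %.1f mm thick, HU [%d, %d]\n",
              d[1], d[2], d[3], x$pixel_spacing, x$slice_thickness,
              round(min(x$voxels)), round(max(x$voxels))))
  invisible(x)
}

#' @export
print.muscle_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<muscle_mask> %d x %d x %d slices, %d voxels set\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

check_congruent <- function(slab, mask) {
  if (!identical(dim(slab$voxels), dim(mask$voxels)))
    stop("slab and mask shapes differ: ",
         paste(dim(slab$voxels), collapse = "x"), " vs ",
         paste(dim(mask$voxels), collapse = "x"), call. = FALSE)
  invisible(TRUE)
}

#' Read and write CT slabs and masks as NIfTI
#'
#' HU volumes are stored as signed 16-bit integers, masks as unsigned bytes;
#' voxel geometry travels in the NIfTI `pixdim` field.
#'
#' @param slab a [ct_slab()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_*` return `path` invisibly; `read_ct_slab` returns a
#'   [ct_slab()]; `read_muscle_mask` a [muscle_mask()].
#' @export
write_ct_slab <- function(slab, path) {
  img <- RNifti::asNifti(slab$voxels)
  RNifti::pixdim(img) <- c(slab$pixel_spacing, slab$pixel_spacing,
                           slab$slice_thickness)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_ct_slab
#' @export
read_ct_slab <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  ct_slab(array(as.numeric(img), dim = dim(img)),
          pixel_spacing = pd[1], slice_thickness = pd[3])
}

#' @param mask a [muscle_mask()].
#' @rdname write_ct_slab
#' @export
write_muscle_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$voxels)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_ct_slab
#' @export
read_muscle_mask <- function(path) {
  img <- RNifti::readNifti(path)
  muscle_mask(array(as.integer(img), dim = dim(img)))
}
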