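radiomics_channels <- c("Original", "Wavelet(LL)", "Wavelet(LH)",
                        "Wavelet(HL)", "Wavelet(HH)")

#' Radiomics extraction settings
#'
#' @param n_bins gray levels for texture discretization (per channel, over
#'   the pooled in-mask range of the slab).
#' @param distance GLCM pair offset in voxels.
#' @param wavelet compute the four wavelet channels (`TRUE` gives the full
#'   253-feature vector; `FALSE` restricts to the `Original` channel).
#' @return A list of class `radiomics_config`.
#' @export
radiomics_config <- function(n_bins = 32, distance = 1, wavelet = TRUE) {
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  if (distance < 1) stop("`distance` must be >= 1", call. = FALSE)
  structure(list(n_bins = n_bins, distance = distance, wavelet = wavelet),
            class = "radiomics_config")
}

#' Names of the full radiomics feature catalog
#'
#' The 253-feature registry: 18 shape features plus, for each of the five
#' image channels (original + four Haar subbands), 14 first-order, 22 GLCM
#' and 11 GLRLM features. Names follow `<Channel>_<Family>_<Feature>`
#' (shape features are channel-independent and prefixed `Shape_`).
#'
#' @param config a [radiomics_config()].
#' @return Character vector of feature names (length 253 by default).
#' @examples
#' length(radiomics_feature_names())
#' @export
radiomics_feature_names <- function(config = radiomics_config()) {
  chans <- if (config$wavelet) radiomics_channels else radiomics_channels[1]
  c(paste0("Shape_", shape_names),
    unlist(lapply(chans, function(ch) {
      c(paste0(ch, "_FirstOrder_", first_order_names),
        paste0(ch, "_GLCM_", glcm_names),
        paste0(ch, "_GLRLM_", glrlm_names))
    })))
}

# Crop slab + mask to the mask bounding box (small padding); texture and
# first-order features only see in-mask voxels, and shape features are
# translation-invariant, so cropping changes nothing but the run time.
crop_to_mask <- function(vox, mvox, pad = 2L) {
  idx <- which(mvox == 1L, arr.ind = TRUE)
  r <- range(idx[, 1]); c <- range(idx[, 2])
  d <- dim(vox)
  rows <- max(1L, r[1] - pad):min(d[1], r[2] + pad)
  cols <- max(1L, c[1] - pad):min(d[2], c[2] + pad)
  list(vox = vox[rows, cols, , drop = FALSE],
       mask = mvox[rows, cols, , drop = FALSE])
}

#' Extract the radiomics feature vector of one patient
#'
#' Computes the full catalog from the masked muscle voxels of a CT slab:
#' shape on the mask, and per channel (original image and, by default, the
#' four undecimated Haar subbands, all congruent with the mask) the
#' first-order, GLCM and GLRLM families. Texture matrices are built per
#' slice and per in-plane direction, and features averaged over the
#' direction-slice combinations. Deterministic for fixed input.
#'
#' @param slab a [ct_slab()].
#' @param mask a [muscle_mask()] congruent with `slab` (the region the
#'   features describe; typically the contoured ROI).
#' @param config a [radiomics_config()].
#' @return Named numeric vector (253 features with default settings).
#' @examples
#' cfg <- cohort_config(n_patients = 2, seed = 1,
#'                      geometry = list(matrix_size = 96, pixel_spacing = 2.5,
#'                                      slice_thickness = 5, n_slices = 1))
#' ph <- render_phantom(list(true_smi = 40, fat_fraction = 0.1,
#'                           height = 1.6, render_seed = 4), cfg)
#' fv <- extract_features(ph$slab, ph$roi)
#' length(fv)
#' @export
extract_features <- function(slab, mask, config = radiomics_config()) {
  check_congruent(slab, mask)
  if (sum(mask$voxels) == 0) stop("empty mask", call. = FALSE)
  cr <- crop_to_mask(slab$voxels, mask$voxels)
  out <- c(tryCatch(
    shape_features(cr$mask, slab$pixel_spacing, slab$slice_thickness),
    error = function(e) stop("Shape: ", conditionMessage(e), call. = FALSE)))
  names(out) <- paste0("Shape_", shape_names)
  chans <- wavelet_channels(cr$vox)
  if (!config$wavelet) chans <- chans[1]
  inside <- cr$mask == 1L
  for (ch in names(chans)) {
    vals <- chans[[ch]][inside]
    lev <- level_code(chans[[ch]], cr$mask, config$n_bins)
    fam <- tryCatch({
      c(setNames(first_order_features(vals, config$n_bins),
                 paste0(ch, "_FirstOrder_", first_order_names)),
        setNames(glcm_features(lev, config$n_bins, config$distance),
                 paste0(ch, "_GLCM_", glcm_names)),
        setNames(glrlm_features(lev, config$n_bins),
                 paste0(ch, "_GLRLM_", glrlm_names)))
    }, error = function(e)
      stop("channel ", ch, ": ", conditionMessage(e), call. = FALSE))
    out <- c(out, fam)
  }
  if (any(!is.finite(out)))
    stop("non-finite feature values: ",
         paste(head(names(out)[!is.finite(out)], 5), collapse = ", "),
         call. = FALSE)
  out
}

#' Extract the per-patient feature table of a cohort
#'
#' For every patient: load (or lazily re-render from `render_seed`) the CT
#' slab and contoured ROI, segment muscle by HU window to obtain the SMI,
#' and extract the radiomics vector. Radiomics features are computed on the
#' contoured ROI -- including intramuscular fat, whose presence is exactly
#' the heterogeneity the texture families quantify -- while the SMI uses
#' the HU-thresholded (lean) mask.
#'
#' @param cohort a `radsarc_cohort` from [generate_cohort()], or a manifest
#'   data frame with the same columns.
#' @param config a [radiomics_config()].
#' @param hu_window muscle segmentation window in HU.
#' @param features_on `"roi"` (default) or `"muscle"`: compute radiomics on
#'   the contoured ROI or on the thresholded muscle mask.
#' @param verbose print a progress line every 50 patients.
#' @return Data frame: `id`, `smi`, then one column per radiomics feature.
#' @export
extract_cohort_features <- function(cohort, config = radiomics_config(),
                                    hu_window = c(-29, 150),
                                    features_on = c("roi", "muscle"),
                                    verbose = FALSE) {
  features_on <- match.arg(features_on)
  manifest <- if (inherits(cohort, "radsarc_cohort")) cohort$manifest
              else cohort
  gen_cfg <- if (inherits(cohort, "radsarc_cohort")) cohort$config else NULL
  n <- nrow(manifest)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- manifest[i, ]
    if (!is.na(p$image_path) && file.exists(p$image_path)) {
      slab <- read_ct_slab(p$image_path)
      roi <- read_muscle_mask(p$mask_path)
    } else {
      if (is.null(gen_cfg))
        stop("patient ", p$id, ": no image on disk and no generator config ",
             "to re-render from", call. = FALSE)
      ph <- render_phantom(p, gen_cfg)
      slab <- ph$slab; roi <- ph$roi
    }
    seg <- segment_smi(slab, roi, p$height, hu_window[1], hu_window[2])
    fmask <- if (features_on == "roi") roi else seg$mask
    fv <- extract_features(slab, fmask, config)
    rows[[i]] <- c(smi = unname(seg$smi), fv)
    if (verbose && i %% 50 == 0)
      message(sprintf("extracted %d / %d patients", i, n))
  }
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  cbind(data.frame(id = manifest$id, stringsAsFactors = FALSE), tab)
}
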