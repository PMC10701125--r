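local_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_cohort_config(n_slices = 3)
      cache <<- render_phantom(list(true_smi = 42, fat_fraction = 0.2,
                                    height = 1.68, render_seed = 77), cfg)
    }
    cache
  }
})

test_that("the catalog holds exactly 253 uniquely named, finite features", {
  ph <- local_phantom()
  fv <- extract_features(ph$slab, ph$roi)
  expect_length(fv, 253)
  expect_identical(names(fv), radiomics_feature_names())
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_true(all(is.finite(fv)))
  # the features the selection literature names must exist
  expect_true(all(c("Wavelet(LL)_GLCM_Correlation",
                    "Wavelet(LL)_GLRLM_SRLGE",
                    "Wavelet(HL)_GLRLM_SRE") %in% names(fv)))
})

test_that("catalog arithmetic: 18 shape + 5 x (14 + 22 + 11)", {
  nm <- radiomics_feature_names()
  expect_length(grep("^Shape_", nm), 18)
  for (ch in c("Original", "Wavelet\\(LL\\)", "Wavelet\\(LH\\)",
               "Wavelet\\(HL\\)", "Wavelet\\(HH\\)")) {
    expect_length(grep(paste0("^", ch, "_FirstOrder_"), nm), 14)
    expect_length(grep(paste0("^", ch, "_GLCM_"), nm), 22)
    expect_length(grep(paste0("^", ch, "_GLRLM_"), nm), 11)
  }
  expect_length(radiomics_feature_names(radiomics_config(wavelet = FALSE)),
                18 + 47)
})

test_that("extraction is deterministic", {
  ph <- local_phantom()
  expect_identical(extract_features(ph$slab, ph$roi),
                   extract_features(ph$slab, ph$roi))
})

test_that("a constant-HU region degenerates as documented", {
  vox <- array(50, c(16, 16, 2))
  m <- array(0L, c(16, 16, 2)); m[4:12, 4:12, ] <- 1L
  fv <- extract_features(ct_slab(vox, 1), muscle_mask(m))
  for (ch in c("Original", "Wavelet(LL)", "Wavelet(LH)", "Wavelet(HL)",
               "Wavelet(HH)")) {
    expect_equal(unname(fv[paste0(ch, "_GLCM_Contrast")]), 0)
    expect_equal(unname(fv[paste0(ch, "_GLCM_Entropy")]), 0)
    expect_equal(unname(fv[paste0(ch, "_GLCM_Correlation")]), 1)
    expect_equal(unname(fv[paste0(ch, "_FirstOrder_Variance")]), 0)
  }
})

test_that("shape mismatch and empty masks raise errors", {
  ph <- local_phantom()
  expect_error(extract_features(ph$slab,
                                muscle_mask(array(1L, c(4, 4, 1)))),
               "shapes differ")
  empty <- muscle_mask(array(0L, dim(ph$slab$voxels)))
  expect_error(extract_features(ph$slab, empty), "empty mask")
})

test_that("cohort extraction writes an id + SMI + 253 table", {
  cfg <- small_cohort_config(n_patients = 3, seed = 91)
  coh <- generate_cohort(cfg)
  tab <- extract_cohort_features(coh)
  expect_equal(dim(tab), c(3, 2 + 253))
  expect_identical(names(tab)[1:2], c("id", "smi"))
  expect_identical(names(tab)[-(1:2)], radiomics_feature_names())
  # SMI column comes from the segmentation pipeline
  expect_equal(tab$smi, coh$manifest$true_smi, tolerance = 0.02)
})
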