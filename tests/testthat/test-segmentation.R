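test_that("HU window keeps -29..150 inclusively", {
  slab <- toy_slab(c(-1000, -30, -29, 0, 150, 151), nrow = 2)
  roi <- full_mask(slab)
  mask <- apply_hu_threshold(slab, roi)
  kept <- slab$voxels[mask$voxels == 1L]
  expect_setequal(kept, c(-29, 0, 150))
  expect_equal(mask$provenance$hu_window, c(low = -29, high = 150))
})

test_that("window degenerate cases behave", {
  slab <- toy_slab(seq(-500, 700, length.out = 24), nrow = 4)
  empty <- muscle_mask(array(0L, dim(slab$voxels)))
  expect_equal(sum(apply_hu_threshold(slab, empty)$voxels), 0)
  roi <- full_mask(slab)
  ident <- apply_hu_threshold(slab, roi, -1024, 3000)
  expect_identical(ident$voxels, roi$voxels)
  expect_error(apply_hu_threshold(slab, roi, 10, -10), "low")
  bad <- muscle_mask(array(1L, c(2, 2, 1)))
  expect_error(apply_hu_threshold(slab, bad, -29, 150), "shapes differ")
})

test_that("widening the window never removes voxels", {
  set.seed(4)
  slab <- toy_slab(round(rnorm(64, 20, 120)), nrow = 8)
  roi <- muscle_mask(array(rbinom(64, 1, 0.7), c(8, 8, 1)))
  inner <- apply_hu_threshold(slab, roi, -29, 150)
  for (pad in c(10, 50, 400)) {
    outer <- apply_hu_threshold(slab, roi, -29 - pad, 150 + pad)
    expect_true(all(outer$voxels >= inner$voxels))
  }
})

test_that("area converts voxel counts with spacing squared", {
  m <- muscle_mask(array(rep(c(1L, 0L), c(100, 44)), c(12, 12, 1)))
  expect_equal(cross_sectional_area(m, 1)$mean_area, 1.00)
  expect_equal(cross_sectional_area(m, 2)$mean_area, 4.00)
  set.seed(8)
  vox <- array(rbinom(12 * 12 * 5, 1, 0.4), c(12, 12, 5))
  rm <- muscle_mask(vox)
  a <- cross_sectional_area(rm, 0.88)
  # brute-force voxel count oracle
  counts <- sapply(1:5, function(s) sum(vox[, , s] == 1))
  expect_equal(a$per_slice, counts * 0.88^2 / 100)
  # slice order does not change the summary
  perm <- muscle_mask(vox[, , c(3, 1, 5, 2, 4)])
  expect_equal(cross_sectional_area(perm, 0.88)$mean_area, a$mean_area)
  expect_error(cross_sectional_area(
    muscle_mask(array(0L, c(4, 4, 2))), 1), "empty")
})

test_that("SMI is area over height squared", {
  expect_equal(compute_smi(140, 1.70), 140 / 1.70^2, tolerance = 1e-12)
  expect_equal(round(compute_smi(140, 1.70), 2), 48.44)
  expect_equal(compute_smi(280, 1.70), 2 * compute_smi(140, 1.70))
  expect_error(compute_smi(140, 0), "height")
  expect_error(compute_smi(-1, 1.7), "area")
})

test_that("pipeline SMI recovers the generator's SMI on phantoms", {
  cfg <- small_cohort_config(n_patients = 3, seed = 21, n_slices = 5)
  coh <- generate_cohort(cfg)
  for (i in seq_len(3)) {
    p <- coh$manifest[i, ]
    ph <- render_phantom(p, cfg)
    seg <- segment_smi(ph$slab, ph$roi, p$height)
    expect_lt(abs(seg$smi - p$true_smi) / p$true_smi, 0.02)
  }
})
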