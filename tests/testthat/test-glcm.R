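offsets <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                `90` = c(1L, 0L), `135` = c(1L, 1L))

test_that("co-occurrence counts match exhaustive pair enumeration", {
  set.seed(11)
  for (rep in 1:15) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1); nb <- sample(2:4, 1)
    lev <- matrix(sample(0:nb, nr * nc, replace = TRUE), nr, nc)
    for (off in offsets) {
      counts_oracle <- glcm_oracle(lev, nb, off[1], off[2])
      p <- glcm_matrix(lev, nb, offset = off)
      if (sum(counts_oracle) == 0) {
        expect_equal(sum(p), 0)
      } else {
        expect_equal(p, counts_oracle / sum(counts_oracle))
      }
    }
  }
})

test_that("anticorrelated two-level stripes give correlation -1", {
  # rows (1,2) / (1,2): horizontal neighbors always differ
  lev <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  p <- glcm_matrix(lev, 2, offset = c(0L, 1L))
  expect_equal(p, matrix(c(0, 0.5, 0.5, 0), 2))
  f <- glcm_matrix_features(p)
  expect_equal(unname(f["Correlation"]), -1)
})

test_that("constant regions use the degenerate conventions", {
  lev <- array(1L, c(4, 4, 2))
  f <- glcm_features(lev, n_bins = 4)
  expect_equal(unname(f["Correlation"]), 1)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["IMC1"]), 0)
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["MaximumProbability"]), 1)
})

test_that("every GLCM is normalized and symmetric", {
  set.seed(12)
  for (rep in 1:10) {
    lev <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
    for (off in offsets) {
      p <- glcm_matrix(lev, 5, offset = off)
      expect_equal(sum(p), 1)
      expect_equal(p, t(p))
    }
  }
})

test_that("direction-averaged features are invariant to 90-degree rotation", {
  set.seed(13)
  lev <- matrix(sample(1:4, 49, replace = TRUE), 7, 7)
  rot <- t(lev[nrow(lev):1, ])    # 90-degree rotation
  f1 <- glcm_features(lev, 4)
  f2 <- glcm_features(rot, 4)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("masked-out voxels never contribute pairs", {
  lev <- matrix(c(1L, 0L, 2L, 0L, 1L, 0L, 2L, 0L, 1L), 3, 3)
  # only isolated voxels along 0 degrees at distance 1 in column pairs
  p00 <- glcm_matrix(lev, 2, offset = c(0L, 1L))
  expect_equal(sum(p00), 0)  # every horizontal pair crosses a masked voxel
  expect_error(glcm_features(array(0L, c(3, 3, 1)), 2), "no valid")
})

test_that("pair distance is honored", {
  lev <- matrix(c(1L, 2L, 1L, 2L), 1, 4)
  # at distance 2 the 0-degree pairs link equal levels only
  f <- glcm_matrix(lev, 2, offset = c(0L, 2L))
  expect_equal(unname(diag(f)), c(0.5, 0.5))
})
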