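test_that("config validation errors name the offending field", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(n_patients = 10, male_fraction = 1.4),
               "male_fraction")
  expect_error(cohort_config(n_patients = 10,
                             smi_dist = list(male = c(mean = 49, sd = 0),
                                             female = c(mean = 41, sd = 6))),
               "smi_dist")
  expect_error(cohort_config(n_patients = 10,
                             fat_fraction_shape = c(-1, 8)),
               "fat_fraction_shape")
})

test_that("seeded cohorts are byte-identical across runs", {
  cfg <- cohort_config(n_patients = 12, seed = 42)
  d1 <- file.path(tempdir(), "coh_a")
  on.exit(unlink(d1, recursive = TRUE))
  generate_cohort(cfg, out_dir = d1, write_images = FALSE)
  first <- readBin(file.path(d1, "cohort.csv"), "raw", 1e6)
  generate_cohort(cfg, out_dir = d1, write_images = FALSE)
  expect_identical(readBin(file.path(d1, "cohort.csv"), "raw", 1e6), first)
  # and a different seed changes the draw
  m3 <- generate_cohort(cohort_config(n_patients = 12, seed = 43))$manifest
  m1 <- read.csv(file.path(d1, "cohort.csv"))
  expect_false(identical(m1$true_smi, m3$true_smi))
})

test_that("toxicity prevalence matches the 0.30 target", {
  # n = 400 cohort draw (3 SE band around 0.30)
  coh <- generate_cohort(cohort_config(n_patients = 400, seed = 7))
  se <- sqrt(0.3 * 0.7 / 400)
  expect_lt(abs(mean(coh$manifest$toxicity) - 0.30), 3 * se)
  # n = 10,000 label redraw under the same covariate model
  big <- generate_cohort(cohort_config(n_patients = 10000, seed = 8))
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(big$manifest$toxicity) - 0.30), 3 * se)
})

test_that("null toxicity coefficients give probability one half", {
  cfg <- cohort_config(n_patients = 10,
                       toxicity_coefs = c(beta0 = 0, beta1 = 0, beta2 = 0))
  p <- toxicity_probability(c(30, 47, 60), c(0.05, 0.2, 0.5), cfg)
  expect_equal(p, rep(0.5, 3))
})

test_that("a positive SMI effect lowers mean SMI in the toxic group", {
  coh <- generate_cohort(cohort_config(n_patients = 10000, seed = 5))
  m <- coh$manifest
  expect_lt(mean(m$true_smi[m$toxicity == 1]),
            mean(m$true_smi[m$toxicity == 0]))
})

test_that("raising the SMI coefficient raises the oracle AUC of SMI", {
  aucs <- vapply(c(0.2, 1.4), function(b1) {
    cfg <- cohort_config(n_patients = 4000, seed = 31,
                         toxicity_coefs = c(beta0 = -1, beta1 = b1,
                                            beta2 = 0.6))
    m <- generate_cohort(cfg)$manifest
    roc_auc(-m$true_smi, m$toxicity)$auc
  }, numeric(1))
  expect_gt(aucs[2], aucs[1] + 0.05)
})

test_that("cohort SMI moments converge to the configured mixture", {
  cfg <- cohort_config(n_patients = 8000, seed = 13)
  m <- generate_cohort(cfg)$manifest
  # pooled mixture: 0.7 N(49, 7) + 0.3 N(41, 6)
  mu <- 0.7 * 49 + 0.3 * 41
  sdv <- sqrt(0.7 * 49 + 0.3 * 36 + 0.7 * 0.3 * 64)
  n <- nrow(m)
  expect_lt(abs(mean(m$true_smi) - mu), 3 * sdv / sqrt(n))
  expect_lt(abs(sd(m$true_smi) - sdv), 3 * sdv / sqrt(2 * n))
  expect_equal(m$bmi, round(m$weight / m$height^2, 1), tolerance = 0.06)
})

test_that("phantom construction honors tissue HU and geometry", {
  cfg <- small_cohort_config(
    hu_params = list(muscle = c(mean = 50, sd = 0),
                     fat = c(mean = -100, sd = 0),
                     bone = c(mean = 400, sd = 0),
                     air = c(mean = -1000, sd = 0)))
  pat <- list(true_smi = 45, fat_fraction = 0, height = 1.70,
              render_seed = 2)
  ph <- render_phantom(pat, cfg)
  # zero-variance, zero-infiltration muscle sits exactly at its mean HU
  expect_true(all(ph$slab$voxels[ph$roi$voxels == 1L] == 50))
  # air is exactly -1000 outside the body ellipse (image corner)
  expect_equal(ph$slab$voxels[1, 1, 1], -1000)
  corner <- ph$slab$voxels[1:10, 1:10, ]
  expect_true(all(corner == -1000))
  # ROI area matches the requested SMI (fat_fraction = 0 so ROI = lean)
  area <- cross_sectional_area(ph$roi, cfg$geometry$pixel_spacing)$mean_area
  expect_lt(abs(area / 1.70^2 - 45) / 45, 0.02)
})

test_that("infeasible muscle areas raise a geometry error", {
  cfg <- small_cohort_config()
  expect_error(render_phantom(list(true_smi = 95, fat_fraction = 0.5,
                                   height = 1.95, render_seed = 1), cfg),
               "exceeds the body ellipse")
})

test_that("lean (thresholded) area recovers true SMI under infiltration", {
  cfg <- small_cohort_config(n_slices = 5)
  for (f in c(0.1, 0.3)) {
    pat <- list(true_smi = 44, fat_fraction = f, height = 1.65,
                render_seed = 100 + round(100 * f))
    ph <- render_phantom(pat, cfg)
    seg <- segment_smi(ph$slab, ph$roi, pat$height)
    expect_lt(abs(seg$smi - pat$true_smi) / pat$true_smi, 0.02)
  }
})

test_that("iid and blob infiltration hit the requested fat fraction", {
  for (mode in c("blob", "iid")) {
    cfg <- small_cohort_config(infiltration = mode)
    pat <- list(true_smi = 44, fat_fraction = 0.25, height = 1.65,
                render_seed = 9)
    ph <- render_phantom(pat, cfg)
    hu <- ph$slab$voxels[ph$roi$voxels == 1L]
    frac_fat <- mean(hu < -29)
    expect_lt(abs(frac_fat - 0.25), if (mode == "blob") 0.02 else 0.05)
  }
})

test_that("YAML round trip reproduces a cohort config", {
  cfg <- cohort_config(n_patients = 9, seed = 3, male_fraction = 0.6)
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  yaml::write_yaml(list(n_patients = 9, seed = 3, male_fraction = 0.6),
                   path)
  cfg2 <- read_cohort_config(path)
  expect_identical(generate_cohort(cfg)$manifest,
                   generate_cohort(cfg2)$manifest)
  yaml::write_yaml(list(n_patients = 9, bogus_field = 1), path)
  expect_error(read_cohort_config(path), "bogus_field")
})
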