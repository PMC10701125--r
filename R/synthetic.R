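#' Configuration for a synthetic CT-phantom cohort
#'
#' Defines the study conditions the generator emulates: a 512 x 512 axial
#' matrix, 5 consecutive L3-level slices, HU-valued tissue compartments
#' (muscle ~ 50 HU, fat ~ -100 HU, bone, air at -1000), sex-specific SMI
#' distributions whose 70/30 male/female mixture matches a pooled mean near
#' 46.8 cm2/m2 (SD ~ 7.5), Beta-distributed muscle-fat infiltration driving
#' texture heterogeneity, and a Bernoulli toxicity outcome from a logistic
#' model on standardized (negated) SMI and fat fraction with prevalence
#' close to 0.30.
#'
#' @param n_patients cohort size (>= 2).
#' @param seed master seed; every downstream draw derives from it.
#' @param male_fraction probability that a patient is male.
#' @param height_dist per-sex mean/SD of height in m.
#' @param smi_dist per-sex mean/SD of true SMI in cm2/m2.
#' @param bmi_dist mean/SD of BMI (kg/m2); weight is derived as BMI x height^2.
#' @param age_dist mean/SD of age in years.
#' @param fat_fraction_shape Beta shape parameters of the muscle-fat
#'   infiltration fraction.
#' @param hu_params per-tissue HU mean/SD for muscle, fat, bone, air.
#' @param geometry matrix size (voxels), pixel spacing (mm), slice
#'   thickness (mm) and number of slices.
#' @param toxicity_coefs logit-scale coefficients `c(beta0, beta1, beta2)`:
#'   intercept, effect per SD of negated SMI, effect per SD of fat fraction.
#' @param infiltration `"blob"` (spatially correlated fat infiltration via
#'   smoothed noise, the default) or `"iid"` (voxelwise independent).
#' @param blob_sigma Gaussian smoothing scale (pixels) of the blob field.
#' @param body phantom geometry in mm: body-ellipse semi-axes `a`/`b`,
#'   inner radius of the muscle ring, vertebral bone radius.
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_patients = 10, seed = 1)
#' cfg$geometry$matrix_size
#' @export
cohort_config <- function(n_patients = 200,
                          seed = 1,
                          male_fraction = 0.7,
                          height_dist = list(male = c(mean = 1.70, sd = 0.06),
                                             female = c(mean = 1.59, sd = 0.06)),
                          smi_dist = list(male = c(mean = 49, sd = 7),
                                          female = c(mean = 41, sd = 6)),
                          bmi_dist = c(mean = 23.2, sd = 2.8),
                          age_dist = c(mean = 55, sd = 10),
                          fat_fraction_shape = c(2, 8),
                          hu_params = list(muscle = c(mean = 50, sd = 12),
                                           fat = c(mean = -100, sd = 20),
                                           bone = c(mean = 400, sd = 80),
                                           air = c(mean = -1000, sd = 0)),
                          geometry = list(matrix_size = 512,
                                          pixel_spacing = 0.88,
                                          slice_thickness = 5,
                                          n_slices = 5),
                          toxicity_coefs = c(beta0 = -1.0, beta1 = 0.8,
                                             beta2 = 0.6),
                          infiltration = c("blob", "iid"),
                          blob_sigma = 3,
                          body = list(a = 180, b = 150, ring_inner = 60,
                                      bone_radius = 15)) {
  fail <- function(field, why)
    stop(sprintf("invalid config field `%s`: %s", field, why), call. = FALSE)
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 2 ||
      n_patients != round(n_patients))
    fail("n_patients", "must be an integer >= 2")
  if (!is.numeric(seed) || length(seed) != 1) fail("seed", "must be a number")
  if (male_fraction < 0 || male_fraction > 1)
    fail("male_fraction", "must lie in [0, 1]")
  for (s in c("male", "female")) {
    if (height_dist[[s]]["sd"] <= 0) fail("height_dist", "SDs must be > 0")
    if (smi_dist[[s]]["sd"] <= 0) fail("smi_dist", "SDs must be > 0")
    if (smi_dist[[s]]["mean"] <= 0) fail("smi_dist", "means must be > 0")
  }
  if (bmi_dist["sd"] <= 0) fail("bmi_dist", "SD must be > 0")
  if (age_dist["sd"] <= 0) fail("age_dist", "SD must be > 0")
  if (any(fat_fraction_shape <= 0))
    fail("fat_fraction_shape", "Beta shapes must be > 0")
  for (t in c("muscle", "fat", "bone", "air"))
    if (is.null(hu_params[[t]]) || hu_params[[t]]["sd"] < 0)
      fail("hu_params", paste0("tissue `", t, "` needs mean and SD >= 0"))
  if (geometry$matrix_size < 16) fail("geometry", "matrix_size too small")
  if (geometry$pixel_spacing <= 0) fail("geometry", "pixel_spacing must be > 0")
  if (geometry$slice_thickness <= 0)
    fail("geometry", "slice_thickness must be > 0")
  if (geometry$n_slices < 1) fail("geometry", "n_slices must be >= 1")
  infiltration <- match.arg(infiltration)
  if (blob_sigma <= 0) fail("blob_sigma", "must be > 0")
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              male_fraction = male_fraction, height_dist = height_dist,
              smi_dist = smi_dist, bmi_dist = bmi_dist, age_dist = age_dist,
              fat_fraction_shape = fat_fraction_shape, hu_params = hu_params,
              geometry = geometry, toxicity_coefs = toxicity_coefs,
              infiltration = infiltration, blob_sigma = blob_sigma,
              body = body)
  class(cfg) <- "cohort_config"
  cfg
}

#' Read a cohort configuration from YAML
#'
#' Fields present in the file override the defaults of [cohort_config()].
#'
#' @param path YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  # YAML gives named lists where the defaults use named vectors
  revec <- function(x) if (is.list(x) && all(vapply(x, is.numeric, TRUE)) &&
                           all(lengths(x) == 1)) unlist(x) else x
  for (nm in c("bmi_dist", "age_dist", "toxicity_coefs",
               "fat_fraction_shape")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- revec(raw[[nm]])
  }
  for (nm in c("height_dist", "smi_dist", "hu_params")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- lapply(raw[[nm]], revec)
  }
  do.call(cohort_config, raw)
}

# Analytic moments of the pooled SMI mixture and the Beta fat fraction.
# These are the cohort-level standardization constants of the toxicity model,
# so per-patient labels do not depend on who else is in the sample.
smi_pooled_moments <- function(config) {
  p <- config$male_fraction
  mm <- config$smi_dist$male["mean"]; sm <- config$smi_dist$male["sd"]
  mf <- config$smi_dist$female["mean"]; sf <- config$smi_dist$female["sd"]
  mu <- p * mm + (1 - p) * mf
  v <- p * sm^2 + (1 - p) * sf^2 + p * (1 - p) * (mm - mf)^2
  c(mean = unname(mu), sd = unname(sqrt(v)))
}

fat_fraction_moments <- function(config) {
  a <- config$fat_fraction_shape[1]; b <- config$fat_fraction_shape[2]
  c(mean = a / (a + b), sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
}

#' Toxicity model of the synthetic cohort
#'
#' The ground-truth outcome model: severe-toxicity probability is
#' `plogis(beta0 + beta1 * z(-SMI) + beta2 * z(f))` where z-scores use the
#' analytic cohort-level moments from the configuration (lower muscle mass
#' and higher fat infiltration both raise risk). `assign_toxicity` draws
#' Bernoulli labels from those probabilities using the current RNG stream.
#'
#' @param smi true SMI values (cm2/m2), vectorized.
#' @param fat_fraction infiltration fractions in \[0, 1\], same length.
#' @param config a [cohort_config()].
#' @return `toxicity_probability`: numeric probabilities;
#'   `assign_toxicity`: integer 0/1 labels.
#' @examples
#' cfg <- cohort_config(n_patients = 10, seed = 1)
#' toxicity_probability(c(40, 55), c(0.3, 0.1), cfg)
#' @export
toxicity_probability <- function(smi, fat_fraction, config) {
  b <- config$toxicity_coefs
  sm <- smi_pooled_moments(config)
  fm <- fat_fraction_moments(config)
  z_negsmi <- (sm["mean"] - smi) / sm["sd"]
  z_fat <- (fat_fraction - fm["mean"]) / fm["sd"]
  unname(plogis(b[1] + b[2] * z_negsmi + b[3] * z_fat))
}

#' @rdname toxicity_probability
#' @export
assign_toxicity <- function(smi, fat_fraction, config) {
  p <- toxicity_probability(smi, fat_fraction, config)
  rbinom(length(p), 1L, p)
}

# Separable Gaussian blur with replicated edges, used for the spatially
# correlated ("blob") fat-infiltration field.
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  shift_rows <- function(x, s) {
    n <- nrow(x)
    idx <- pmin(pmax(seq_len(n) + s, 1L), n)
    x[idx, , drop = FALSE]
  }
  pass <- function(x) {
    out <- x * k[r + 1]
    for (s in seq_len(r)) {
      out <- out + k[r + 1 + s] * shift_rows(x, s) +
        k[r + 1 - s] * shift_rows(x, -s)
    }
    out
  }
  t(pass(t(pass(m))))
}

#' Render one synthetic L3 CT slab and its muscle ROI
#'
#' The phantom is an axial abdomen proxy: an elliptical body of fat-HU
#' voxels, a circular muscle ring (paraspinal/abdominal-wall proxy), a
#' central vertebral bone disk, and air at exactly -1000 HU outside the
#' body. Muscle-ring voxels draw HU from the two-component mixture
#' `(1 - f) Normal(muscle) + f Normal(fat)` with `f` the patient's fat
#' fraction; in the default blob mode the infiltrated voxels are selected
#' by thresholding a smoothed noise field, giving spatially coherent fat
#' streaks. The ring is sized so that its *lean* area (the `(1 - f)` muscle
#' component, i.e. what HU-window segmentation recovers) divided by height
#' squared equals `true_smi`; the contoured ROI includes the intramuscular
#' fat, as a real muscle contour does.
#'
#' @param patient a list or one-row data frame with `true_smi`,
#'   `fat_fraction`, `height`, and optionally `render_seed`.
#' @param config a [cohort_config()].
#' @return List with `slab` (a [ct_slab()]) and `roi` (a [muscle_mask()]).
#' @examples
#' cfg <- cohort_config(n_patients = 2, seed = 1,
#'                      geometry = list(matrix_size = 128, pixel_spacing = 2,
#'                                      slice_thickness = 5, n_slices = 2))
#' ph <- render_phantom(list(true_smi = 45, fat_fraction = 0.2,
#'                           height = 1.7, render_seed = 9), cfg)
#' dim(ph$slab$voxels)
#' @export
render_phantom <- function(patient, config) {
  if (is.null(patient$true_smi) || is.null(patient$fat_fraction) ||
      is.null(patient$height))
    stop("patient needs `true_smi`, `fat_fraction` and `height`",
         call. = FALSE)
  if (!is.null(patient$render_seed)) set.seed(patient$render_seed)
  g <- config$geometry; b <- config$body; hu <- config$hu_params
  n <- g$matrix_size; sp <- g$pixel_spacing
  f <- patient$fat_fraction
  stopifnot(f >= 0, f < 1)

  # mm coordinates of voxel centers, origin at image center
  cc <- ((seq_len(n)) - (n + 1) / 2) * sp
  x2 <- matrix(cc^2, n, n, byrow = FALSE)   # row offsets
  y2 <- matrix(cc^2, n, n, byrow = TRUE)
  r2 <- x2 + y2
  body_mask <- (x2 / b$a^2 + y2 / b$b^2) <= 1

  lean_area_mm2 <- patient$true_smi * patient$height^2 * 100
  comp_area_mm2 <- lean_area_mm2 / (1 - f)
  ri <- b$ring_inner
  ro <- sqrt(comp_area_mm2 / pi + ri^2)
  if (ro > min(b$a, b$b) - 2 * sp)
    stop(sprintf(paste0("requested muscle area (%.0f mm2, outer radius ",
                        "%.0f mm) exceeds the body ellipse"),
                 comp_area_mm2, ro), call. = FALSE)
  ring <- r2 >= ri^2 & r2 <= ro^2
  bone <- r2 <= b$bone_radius^2
  ring_idx <- which(ring)
  n_ring <- length(ring_idx)
  n_fat <- round(f * n_ring)

  # blob field support: ring bounding box
  rows <- range(which(rowSums(ring) > 0)); cols <- range(which(colSums(ring) > 0))

  vox <- array(0, c(n, n, g$n_slices))
  mask <- array(0L, c(n, n, g$n_slices))
  for (s in seq_len(g$n_slices)) {
    sl <- matrix(hu$air["mean"], n, n)
    nb <- sum(body_mask)
    sl[body_mask] <- rnorm(nb, hu$fat["mean"], hu$fat["sd"])
    hu_ring <- rnorm(n_ring, hu$muscle["mean"], hu$muscle["sd"])
    if (n_fat > 0) {
      if (config$infiltration == "blob") {
        noise <- matrix(rnorm((rows[2] - rows[1] + 1) *
                              (cols[2] - cols[1] + 1)),
                        rows[2] - rows[1] + 1)
        field <- gaussian_blur(noise, config$blob_sigma)
        full <- matrix(-Inf, n, n)
        full[rows[1]:rows[2], cols[1]:cols[2]] <- field
        vals <- full[ring_idx]
        fat_sel <- order(vals, decreasing = TRUE)[seq_len(n_fat)]
      } else {
        fat_sel <- which(runif(n_ring) < f)
        n_fat <- length(fat_sel)
      }
      if (n_fat > 0)
        hu_ring[fat_sel] <- rnorm(n_fat, hu$fat["mean"], hu$fat["sd"])
    }
    sl[ring_idx] <- hu_ring
    nb2 <- sum(bone)
    sl[bone] <- rnorm(nb2, hu$bone["mean"], hu$bone["sd"])
    vox[, , s] <- round(sl)
    msl <- matrix(0L, n, n); msl[ring_idx] <- 1L
    mask[, , s] <- msl
  }
  vox[vox < -1024] <- -1024; vox[vox > 3000] <- 3000
  list(slab = ct_slab(vox, pixel_spacing = sp,
                      slice_thickness = g$slice_thickness),
       roi = muscle_mask(mask, provenance = list(source = "phantom ring")))
}

#' Generate a synthetic phantom cohort
#'
#' Draws patient covariates (sex, height, BMI-derived weight, age, true SMI,
#' fat-infiltration fraction), assigns ground-truth toxicity labels from the
#' logistic outcome model, and optionally renders and writes every patient's
#' CT slab and muscle ROI as NIfTI. Fully reproducible from `config$seed`;
#' each patient also carries a private `render_seed` so phantoms can be
#' re-rendered individually (and lazily) without replaying the whole cohort.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory for the manifest (`cohort.csv`) and, if
#'   `write_images`, the `images/` and `masks/` NIfTI trees. `NULL` keeps
#'   everything in memory.
#' @param write_images render and write phantoms now (default when
#'   `out_dir` is given). When `FALSE`, phantoms are rendered on demand from
#'   `render_seed` by downstream steps.
#' @return List of class `radsarc_cohort`: `manifest` (one row per patient),
#'   `config`, `dir`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 7))
#' coh$manifest$toxicity
#' @export
generate_cohort <- function(config, out_dir = NULL,
                            write_images = !is.null(out_dir)) {
  stopifnot(inherits(config, "cohort_config"))
  if (write_images && is.null(out_dir))
    stop("`write_images = TRUE` needs `out_dir`", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_patients
  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")
  height <- ifelse(sex == "male",
                   rnorm(n, config$height_dist$male["mean"],
                         config$height_dist$male["sd"]),
                   rnorm(n, config$height_dist$female["mean"],
                         config$height_dist$female["sd"]))
  # truncate the extreme tails so every phantom fits the body ellipse
  height <- pmin(pmax(height, 1.30), 1.90)
  smi <- ifelse(sex == "male",
                rnorm(n, config$smi_dist$male["mean"],
                      config$smi_dist$male["sd"]),
                rnorm(n, config$smi_dist$female["mean"],
                      config$smi_dist$female["sd"]))
  smi <- pmin(pmax(smi, 20), 75)
  bmi <- pmax(rnorm(n, config$bmi_dist["mean"], config$bmi_dist["sd"]), 14)
  weight <- round(bmi * height^2, 1)
  bmi <- round(weight / height^2, 1)
  age <- round(pmin(pmax(rnorm(n, config$age_dist["mean"],
                               config$age_dist["sd"]), 25), 85))
  fat <- rbeta(n, config$fat_fraction_shape[1], config$fat_fraction_shape[2])
  fat <- pmin(fat, 0.45)
  prob <- toxicity_probability(smi, fat, config)
  tox <- rbinom(n, 1L, prob)
  render_seed <- sample.int(.Machine$integer.max - 1L, n)
  manifest <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    sex = sex,
    age = age,
    height = round(height, 3),
    weight = weight,
    bmi = bmi,
    true_smi = round(smi, 3),
    fat_fraction = round(fat, 4),
    true_prob = round(prob, 6),
    toxicity = tox,
    render_seed = render_seed,
    image_path = NA_character_,
    mask_path = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (write_images) {
      dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
      dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
      for (i in seq_len(n)) {
        ph <- render_phantom(manifest[i, ], config)
        ip <- file.path(out_dir, "images",
                        paste0(manifest$id[i], ".nii.gz"))
        mp <- file.path(out_dir, "masks",
                        paste0(manifest$id[i], "_mask.nii.gz"))
        write_ct_slab(ph$slab, ip)
        write_muscle_mask(ph$roi, mp)
        manifest$image_path[i] <- ip
        manifest$mask_path[i] <- mp
      }
    }
    write.csv(manifest, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  }
  structure(list(manifest = manifest, config = config, dir = out_dir),
            class = "radsarc_cohort")
}

#' @export
print.radsarc_cohort <- function(x, ...) {
  cat(sprintf("<radsarc_cohort> %d patients, prevalence %.3f, seed %d\n",
              nrow(x$manifest), mean(x$manifest$toxicity), x$config$seed))
  invisible(x)
}
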