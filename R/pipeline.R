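#' Split a cohort into training and validation arms
#'
#' Seeded simple randomization: `round(ratio * n)` patients train, the rest
#' validate. Optionally stratified by outcome so both arms keep the event
#' rate.
#'
#' @param manifest cohort manifest data frame.
#' @param ratio training fraction in (0, 1).
#' @param seed RNG seed for the assignment.
#' @param stratify_by optional column name (e.g. `"toxicity"`) to stratify
#'   on.
#' @return The manifest with a `split` column (`"train"`/`"validation"`).
#' @examples
#' m <- data.frame(id = 1:164)
#' table(split_cohort(m, 0.7, seed = 1)$split)  # 115 / 49
#' @export
split_cohort <- function(manifest, ratio = 0.7, seed = 1,
                         stratify_by = NULL) {
  n <- nrow(manifest)
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must be in (0, 1)",
                                     call. = FALSE)
  n_train <- round(ratio * n)
  if (n_train < 2 || n - n_train < 2)
    stop("degenerate split: fewer than 2 patients in an arm", call. = FALSE)
  set.seed(seed)
  split <- rep("validation", n)
  if (is.null(stratify_by)) {
    split[sample.int(n, n_train)] <- "train"
  } else {
    g <- manifest[[stratify_by]]
    for (lev in unique(g)) {
      idx <- which(g == lev)
      split[sample(idx, round(ratio * length(idx)))] <- "train"
    }
  }
  manifest$split <- split
  manifest
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the synthetic-cohort
#' conditions, the radiomics settings, the HU segmentation window, the
#' train:validation ratio and the seeds for splitting and cross-validation.
#'
#' @param out_dir directory all artifacts are written to.
#' @param cohort a [cohort_config()].
#' @param radiomics a [radiomics_config()].
#' @param hu_window muscle HU window.
#' @param split_ratio training fraction.
#' @param split_seed,cv_seed seeds for the cohort split and the LASSO fold
#'   assignment.
#' @param stratify_split stratify the split by outcome.
#' @param k_folds LASSO cross-validation folds.
#' @param dca_thresholds decision-curve threshold grid.
#' @param ci_method AUC confidence-interval method.
#' @param write_images write phantom NIfTI files during `simulate` (off by
#'   default; phantoms re-render lazily from their seeds).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "radsarc_run",
                            cohort = cohort_config(),
                            radiomics = radiomics_config(),
                            hu_window = c(-29, 150),
                            split_ratio = 0.7,
                            split_seed = 20, cv_seed = 30,
                            stratify_split = FALSE,
                            k_folds = 5,
                            dca_thresholds = seq(0.01, 0.99, by = 0.01),
                            ci_method = "delong",
                            write_images = FALSE) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(radiomics, "radiomics_config"))
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("invalid config field `split_ratio`: must be in (0, 1)",
         call. = FALSE)
  cfg <- list(out_dir = out_dir, cohort = cohort, radiomics = radiomics,
              hu_window = hu_window, split_ratio = split_ratio,
              split_seed = split_seed, cv_seed = cv_seed,
              stratify_split = stratify_split, k_folds = k_folds,
              dca_thresholds = dca_thresholds, ci_method = ci_method,
              write_images = write_images)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level scalar fields override [pipeline_config()] defaults; the
#' `cohort` and `radiomics` blocks are forwarded to their own constructors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$cohort)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp), add = TRUE)
    yaml::write_yaml(raw$cohort, tmp)
    args$cohort <- read_cohort_config(tmp)
  }
  if (!is.null(raw$radiomics))
    args$radiomics <- do.call(radiomics_config, raw$radiomics)
  if (!is.null(args$dca_thresholds)) args$dca_thresholds <-
      as.numeric(args$dca_thresholds)
  do.call(pipeline_config, args)
}

config_hash <- function(config) rlang::hash(unclass(config))

stage_log <- function(stage, msg)
  message(sprintf("[radsarc:%s] %s", stage, msg))

artifact_path <- function(config, name) file.path(config$out_dir, name)

require_artifact <- function(config, name, producer) {
  p <- artifact_path(config, name)
  if (!file.exists(p))
    stop("missing artifact `", name, "`: run the `", producer,
         "` stage first", call. = FALSE)
  p
}

stamp_meta <- function(config, stage, extra = list()) {
  mp <- artifact_path(config, "pipeline_meta.json")
  meta <- if (file.exists(mp)) jsonlite::read_json(mp) else list()
  meta[[stage]] <- c(list(config_hash = config_hash(config),
                          seed = config$cohort$seed), extra)
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}

#' Pipeline stages
#'
#' Five independently runnable stages sharing one output directory:
#' `simulate` writes the cohort manifest (and optionally phantom NIfTIs),
#' `extract` the per-patient feature table, `train` the serialized model
#' (preprocessing parameters, LASSO selection, combined and SMI-only
#' coefficients, training Youden cutoff), `evaluate` the evaluation report
#' (AUCs with CIs, confusion metrics, Youden cutoffs, decision-curve
#' arrays per arm and model), and `report` the figures. Every artifact is
#' stamped with the configuration hash and seed in `pipeline_meta.json`.
#'
#' @param config a [pipeline_config()].
#' @return Each stage returns its main artifact invisibly; `run_pipeline`
#'   returns the evaluation report.
#' @export
pipeline_simulate <- function(config) {
  stage_log("simulate", sprintf("generating %d patients (seed %d)",
                                config$cohort$n_patients,
                                config$cohort$seed))
  cohort <- generate_cohort(config$cohort, out_dir = config$out_dir,
                            write_images = config$write_images)
  manifest <- split_cohort(cohort$manifest, config$split_ratio,
                           seed = config$split_seed,
                           stratify_by = if (config$stratify_split)
                             "toxicity" else NULL)
  write.csv(manifest, artifact_path(config, "cohort.csv"),
            row.names = FALSE)
  stamp_meta(config, "simulate",
             list(n = nrow(manifest),
                  prevalence = mean(manifest$toxicity)))
  stage_log("simulate", sprintf("prevalence %.3f; split %s",
                                mean(manifest$toxicity),
                                paste(table(manifest$split)[c("train",
                                                              "validation")],
                                      collapse = "/")))
  invisible(manifest)
}

#' @rdname pipeline_simulate
#' @export
pipeline_extract <- function(config) {
  mp <- require_artifact(config, "cohort.csv", "simulate")
  manifest <- read.csv(mp, stringsAsFactors = FALSE)
  stage_log("extract", sprintf("extracting %d-feature vectors for %d patients",
                               length(radiomics_feature_names(config$radiomics)),
                               nrow(manifest)))
  cohort <- structure(list(manifest = manifest, config = config$cohort,
                           dir = config$out_dir),
                      class = "radsarc_cohort")
  tab <- extract_cohort_features(cohort, config$radiomics,
                                 hu_window = config$hu_window,
                                 verbose = TRUE)
  write.csv(tab, artifact_path(config, "features.csv"), row.names = FALSE)
  stamp_meta(config, "extract", list(n_features = ncol(tab) - 2L))
  invisible(tab)
}

read_feature_table <- function(path) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tab
}

#' @rdname pipeline_simulate
#' @export
pipeline_train <- function(config) {
  fp <- require_artifact(config, "features.csv", "extract")
  mp <- require_artifact(config, "cohort.csv", "simulate")
  features <- read_feature_table(fp)
  manifest <- read.csv(mp, stringsAsFactors = FALSE)
  stopifnot(identical(features$id, manifest$id))
  if (is.null(manifest$split))
    manifest <- split_cohort(manifest, config$split_ratio,
                             seed = config$split_seed)
  tr <- manifest$split == "train"
  y <- manifest$toxicity
  feat_cols <- setdiff(names(features), "id")
  stage_log("train", sprintf("preprocess + LASSO on %d train rows, %d features",
                             sum(tr), length(feat_cols)))
  prep <- fit_preprocess(features[tr, feat_cols])
  xtr <- apply_preprocess(prep, features[tr, feat_cols])
  lasso <- fit_lasso_logistic(xtr, y[tr], k = config$k_folds,
                              seed = config$cv_seed)
  rs_tr <- rad_score(lasso, xtr)
  combined <- fit_combined(features$smi[tr], rs_tr, y[tr])
  smi_only <- glm(y ~ smi, family = binomial(),
                  data = data.frame(y = y[tr], smi = features$smi[tr]))
  prob_tr <- predict(combined,
                     data.frame(smi = features$smi[tr], radscore = rs_tr))
  cutoff <- roc_auc(prob_tr, y[tr])$youden_cutoff
  model <- list(
    config_hash = config_hash(config),
    preprocess = list(features = prep$features,
                      lambda = as.list(prep$lambda),
                      center = as.list(prep$center),
                      scale = as.list(prep$scale),
                      floor = as.list(prep$floor),
                      dropped = prep$dropped),
    lasso = list(lambda = lasso$lambda, intercept = lasso$intercept,
                 coefficients = as.list(lasso$coefficients),
                 k = lasso$k, seed = lasso$seed),
    combined = as.list(combined$coefficients),
    smi_only = as.list(coef(smi_only)),
    youden_cutoff_train = cutoff)
  jsonlite::write_json(model, artifact_path(config, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  stamp_meta(config, "train",
             list(n_selected = length(lasso$selected),
                  lambda = lasso$lambda))
  stage_log("train", sprintf("lambda %.5f, %d features selected",
                             lasso$lambda, length(lasso$selected)))
  invisible(model)
}

# Rebuild in-package objects from the serialized model
model_from_json <- function(path) {
  m <- jsonlite::read_json(path)
  num <- function(x) {
    v <- unlist(x)            # JSON nulls (skipped Box-Cox) drop out here
    setNames(as.numeric(v), names(v))
  }
  prep <- structure(list(
    features = unlist(m$preprocess$features),
    lambda = num(m$preprocess$lambda),
    center = num(m$preprocess$center),
    scale = num(m$preprocess$scale),
    floor = num(m$preprocess$floor),
    dropped = unlist(m$preprocess$dropped)), class = "preprocess_params")
  lasso <- structure(list(
    lambda = m$lasso$lambda, intercept = m$lasso$intercept,
    coefficients = unlist(m$lasso$coefficients),
    selected = names(unlist(m$lasso$coefficients)),
    k = m$lasso$k, seed = m$lasso$seed), class = "rad_lasso")
  combined <- structure(list(coefficients = unlist(m$combined),
                             separation = FALSE, glm = NULL),
                        class = "combined_model")
  list(preprocess = prep, lasso = lasso, combined = combined,
       smi_only = unlist(m$smi_only),
       youden_cutoff_train = m$youden_cutoff_train,
       config_hash = m$config_hash)
}

evaluate_arm <- function(y, prob_combined, prob_smi, cutoff_train, config) {
  res <- list()
  for (mdl in c("combined", "smi")) {
    prob <- if (mdl == "combined") prob_combined else prob_smi
    roc <- roc_auc(prob, y, ci_method = config$ci_method)
    met_own <- classification_metrics(as.integer(prob >= roc$youden_cutoff),
                                      y)
    met_tr <- classification_metrics(as.integer(prob >= cutoff_train), y)
    dca <- decision_curve(prob, y, config$dca_thresholds)
    res[[mdl]] <- list(
      auc = roc$auc, auc_ci = roc$ci,
      youden_cutoff = roc$youden_cutoff,
      metrics_at_own_cutoff = as.list(met_own),
      metrics_at_train_cutoff = as.list(met_tr),
      decision_curve = list(threshold = dca$threshold,
                            net_benefit = dca$net_benefit,
                            nb_all = dca$nb_all))
  }
  res$n <- length(y)
  res$prevalence <- mean(y)
  res
}

#' @rdname pipeline_simulate
#' @export
pipeline_evaluate <- function(config) {
  fp <- require_artifact(config, "features.csv", "extract")
  mp <- require_artifact(config, "cohort.csv", "simulate")
  mj <- require_artifact(config, "model.json", "train")
  features <- read_feature_table(fp)
  manifest <- read.csv(mp, stringsAsFactors = FALSE)
  model <- model_from_json(mj)
  stage_log("evaluate", "scoring training and validation arms")
  xall <- apply_preprocess(model$preprocess,
                           features[setdiff(names(features), "id")])
  rs <- rad_score(model$lasso, xall)
  prob_combined <- predict(model$combined,
                           data.frame(smi = features$smi, radscore = rs))
  prob_smi <- plogis(model$smi_only[1] + model$smi_only[2] * features$smi)
  report <- list(config_hash = config_hash(config),
                 model_hash = model$config_hash,
                 youden_cutoff_train = model$youden_cutoff_train)
  for (arm in c("train", "validation")) {
    sel <- manifest$split == arm
    report[[arm]] <- evaluate_arm(manifest$toxicity[sel],
                                  prob_combined[sel], prob_smi[sel],
                                  model$youden_cutoff_train, config)
  }
  scores <- data.frame(id = manifest$id, split = manifest$split,
                       toxicity = manifest$toxicity,
                       rad_score = rs, prob_combined = prob_combined,
                       prob_smi = prob_smi)
  write.csv(scores, artifact_path(config, "scores.csv"), row.names = FALSE)
  jsonlite::write_json(report, artifact_path(config, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stamp_meta(config, "evaluate",
             list(auc_combined_validation = report$validation$combined$auc))
  stage_log("evaluate",
            sprintf("validation AUC: combined %.3f, SMI-only %.3f",
                    report$validation$combined$auc,
                    report$validation$smi$auc))
  invisible(report)
}

#' @rdname pipeline_simulate
#' @export
pipeline_report <- function(config) {
  rp <- require_artifact(config, "report.json", "evaluate")
  sp <- require_artifact(config, "scores.csv", "evaluate")
  report <- jsonlite::read_json(rp)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stage_log("report", "ggplot2 not installed; skipping figures")
    return(invisible(report))
  }
  scores <- read.csv(sp, stringsAsFactors = FALSE)
  figdir <- artifact_path(config, "figures")
  dir.create(figdir, showWarnings = FALSE, recursive = TRUE)
  for (arm in c("train", "validation")) {
    s <- scores[scores$split == arm, ]
    roc <- roc_auc(s$prob_combined, s$toxicity)
    ggplot2::ggsave(file.path(figdir, paste0("roc_", arm, ".png")),
                    plot_roc(list(combined = roc_auc(s$prob_combined,
                                                     s$toxicity),
                                  smi = roc_auc(s$prob_smi, s$toxicity))),
                    width = 5, height = 5, dpi = 150)
    ggplot2::ggsave(file.path(figdir, paste0("dca_", arm, ".png")),
                    plot_decision_curve(list(
                      combined = decision_curve(s$prob_combined, s$toxicity,
                                                config$dca_thresholds),
                      smi = decision_curve(s$prob_smi, s$toxicity,
                                           config$dca_thresholds))),
                    width = 6, height = 4.5, dpi = 150)
    ggplot2::ggsave(file.path(figdir, paste0("waterfall_", arm, ".png")),
                    plot_waterfall(waterfall(s$rad_score, s$toxicity,
                                             roc$youden_cutoff)),
                    width = 6, height = 4, dpi = 150)
  }
  stage_log("report", paste("figures written to", figdir))
  invisible(report)
}

#' Run the full pipeline
#'
#' Chains `simulate -> extract -> train -> evaluate -> report`. Re-running
#' with an unchanged configuration reproduces every artifact.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of stages to run, in order.
#' @rdname pipeline_simulate
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "extract", "train",
                                    "evaluate", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- NULL
  for (st in stages) {
    out <- switch(st,
                  simulate = pipeline_simulate(config),
                  extract = pipeline_extract(config),
                  train = pipeline_train(config),
                  evaluate = pipeline_evaluate(config),
                  report = pipeline_report(config),
                  stop("unknown stage: ", st, call. = FALSE))
  }
  invisible(out)
}
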