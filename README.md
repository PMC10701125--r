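# radsarc

Skeletal-muscle CT radiomics for predicting severe treatment toxicity.

In patients receiving intensive chemoradiotherapy, low skeletal muscle mass
(sarcopenia) predisposes to severe gastrointestinal toxicity, but the
standard body-composition summary — the **skeletal muscle index**
(SMI = L3 cross-sectional muscle area / height², cm²/m²) — is a sensitive
yet blunt instrument. Muscle *quality* carries extra signal: muscle
depletion goes hand in hand with intramuscular fat deposition, visible on
CT as textural heterogeneity of the muscle compartment. `radsarc`
implements the full analysis pipeline that turns a stack of L3-level CT
slices plus a muscle contour into a validated toxicity risk model:

1. **Segmentation** — muscle voxels by the −29…+150 HU window inside the
   contoured ROI; per-slice cross-sectional area; SMI.
2. **Radiomics** — a 253-feature vector per patient: 18 shape features plus,
   for each of 5 image channels (original + undecimated 2-D Haar subbands
   LL/LH/HL/HH), 14 first-order intensity features, 22 GLCM texture
   features (grey-level co-occurrence, e.g. correlation
   `Σ p(i,j)(i−μx)(j−μy)/(σxσy)`), and 11 GLRLM run-length features
   (e.g. short-run emphasis `SRE = (1/N_r) Σ r(i,j)/j²`).
3. **Modeling** — per-feature Box-Cox/centering/scaling fitted on training
   data only; L1-penalized (LASSO) logistic selection with 5-fold
   stratified cross-validation; the **rad-score** (the coefficient-weighted
   sum of selected radiomics features); a combined two-covariate logistic
   model `logit P(toxicity) = β0 + β1·SMI + β2·rad-score`; odds ratios and
   VIF collinearity diagnostics.
4. **Evaluation** — AUC with DeLong 95% CI, Youden cutoffs, confusion
   metrics and F1, waterfall data, and decision-curve analysis
   (net benefit `TP/N − (FP/N)·p_t/(1−p_t)` against treat-all/treat-none).
5. **Synthetic cohorts** — a CT-phantom generator with known ground truth
   (true SMI, fat-infiltration fraction, true toxicity probability), so the
   whole pipeline is testable end to end without patient data.

## Worked example

```r
library(radsarc)

cfg <- pipeline_config(
  out_dir     = "run1",
  cohort      = cohort_config(n_patients = 570, seed = 1),
  split_ratio = 400 / 570, split_seed = 101, cv_seed = 102)

run_pipeline(cfg, stages = c("simulate", "extract", "train", "evaluate"))
#> [radsarc:simulate] generating 570 patients (seed 1)
#> [radsarc:simulate] prevalence 0.296; split 400/170
#> [radsarc:extract] extracting 253-feature vectors for 570 patients
#> [radsarc:train] preprocess + LASSO on 400 train rows, 254 features
#> [radsarc:train] lambda 0.01814, 11 features selected
#> [radsarc:evaluate] scoring training and validation arms
#> [radsarc:evaluate] validation AUC: combined 0.780, SMI-only 0.767
```

The run leaves `cohort.csv`, `features.csv` (id + SMI + 253 features),
`model.json` (preprocessing parameters, LASSO selection, combined-model
coefficients, training Youden cutoff) and `report.json` in `run1/`. On this
seed the combined model reaches a validation AUC of 0.780 against 0.767
for the SMI alone, and 0.780 is within 0.012 of the oracle AUC computed
from the generator's true event probabilities (0.792) — i.e. the pipeline
recovers nearly all of the recoverable discrimination. Training AUCs are
0.800 (combined) vs 0.742 (SMI-only): the selected texture/intensity
features add real signal beyond muscle quantity, which is the package's
central scientific claim.

Individual stages are plain functions (`apply_hu_threshold()`,
`extract_features()`, `fit_lasso_logistic()`, `roc_auc()`,
`decision_curve()`, `compare_groups()` …) and can be used on their own;
`inst/cli/radsarc` wraps the pipeline for shell use
(`radsarc all --config cfg.yaml --out run1`).

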