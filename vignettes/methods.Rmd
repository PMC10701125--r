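---
title: "Methods: muscle radiomics, the rad-score, and the synthetic phantom cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle radiomics, the rad-score, and the synthetic phantom cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`radsarc` models severe gastrointestinal toxicity risk from two properties
of L3-level skeletal muscle on CT: its *quantity* (the skeletal muscle
index, SMI) and its *quality* (radiomic texture and intensity of the
muscle compartment, which reflect intramuscular fat infiltration). This
vignette documents the modeling choices, the defaults and their units, the
numerical conventions, and what the synthetic phantom cohort does and does
not establish.

## Segmentation and SMI

Muscle voxels are those inside the contoured ROI whose attenuation lies in
the standard skeletal-muscle window of −29 to +150 HU; both bounds are
inclusive, the usual body-composition convention. Per-slice cross-sectional
area is `voxel count × spacing² / 100` (cm²); the scalar area is the
unweighted mean over the five contoured slices — the multi-slice contour
exists precisely to damp single-slice variation in muscle distribution, and
the mean is the reduction that serves that purpose. SMI is area divided by
height squared (cm²/m²). No connected-component cleaning or manual
correction is applied; the ROI is taken as given.

## The 253-feature catalog

The catalog is 18 shape features plus, for each of five image channels,
14 first-order, 22 GLCM and 11 GLRLM features: 18 + 5 × 47 = 253. The
channels are the original image and the four subbands of a single-level
*undecimated* 2-D Haar transform (averaging filter (½, ½), differencing
filter (½, −½), edge-replicated, applied per slice). Because the transform
is undecimated, every subband is congruent with the input and the original
mask applies unchanged — no mask resampling, no interpolation artifacts.

Texture families need discretized intensities: equal-width binning into 32
gray levels over the pooled in-mask range of the slab, per channel. A fixed
bin *count* (rather than fixed width) keeps matrix size bounded across
channels with very different dynamic ranges; 32 levels is the common
radiomics default, fine enough to resolve the muscle/fat bimodality and
coarse enough that a ~15,000-voxel ROI fills the matrix.

GLCM and GLRLM matrices are built per slice and per in-plane direction
(0°, 45°, 90°, 135°; GLCM at distance 1, symmetric, normalized), features
are computed per matrix and then averaged over the direction × slice
combinations. This 2-D-then-average scheme is stated explicitly because a
full 3-D 13-direction aggregation would change values; with 3–5 mm slices
against 0.88 mm pixels, in-plane texture is the physically meaningful
scale. Degenerate-texture conventions: on a constant region GLCM
correlation is 1 and IMC1 is 0; all logarithms are base 2 with
0·log 0 = 0; GLRLM inverse-level/length weights use the 1..32 level codes.

Shape features are 2-D morphometrics of the index (middle) slice in
physical units (areas cm², volume cm³, lengths mm), with per-slice area and
volume using all slices. The perimeter is a Crofton 4-direction estimate
(within 0.5% on a digital disk of radius 50 px, where naive edge counting
errs by ~27% and marching-squares contour length by ~6%). Axis lengths are
the regionprops convention 4·√λ from the pixel-covariance
eigendecomposition; convex area uses the pixel-center hull with a Pick's
theorem boundary correction so convex masks score solidity exactly 1.
Circularity (2√(πA)/P), Compactness1 (A/P²) and Compactness2 (4πA/P²) are
monotone transforms of one another — catalogs in this field conventionally
carry such redundancies, and the LASSO step is indifferent to them.

The catalog is a reconstruction: its families and total are fixed by the
analysis design (and it contains the named selected features
`Wavelet(LL)_GLCM_Correlation`, `Wavelet(LL)_GLRLM_SRLGE`,
`Wavelet(HL)_GLRLM_SRE`), but the identity of every individual feature is
the package's own choice of the standard members of each family.

Radiomics features are computed on the *contoured ROI* (fat included),
while the SMI uses the HU-thresholded lean mask. This split is deliberate:
intramuscular fat is exactly the heterogeneity the texture features are
meant to quantify, so thresholding it away before texture extraction would
remove the signal of interest (`features_on = "muscle"` is available for
comparison).

## Preprocessing, LASSO, and the rad-score

Per feature, on training rows only: a Box-Cox transform
((x^λ − 1)/λ; log x at λ = 0) with λ chosen by profile maximum likelihood on
a grid over [−2, 2] (step 0.05), applied only to strictly positive
features — features with non-positive training values are centered/scaled
only. Then centering to mean 0 and scaling to SD 1. Validation data are
transformed with the frozen training parameters; a validation value at or
below zero for a Box-Cox feature (possible when a feature is positive in
training only by chance) is clipped to half the smallest training value
rather than erroring, keeping the transform total and monotone.
Zero-variance features are dropped with a warning. The Box-Cox step is
implemented in-package because the contract requires the exact closed
forms at λ = 1 and λ = 0 rather than a fudge-zone approximation.

Selection is L1-penalized logistic regression over a penalty path
(`glmnet`, internal standardization off since inputs are already
standardized), with λ chosen by minimum mean cross-validated binomial
deviance over 5 stratified, seeded folds. Minimum-CV rather than the 1-SE
rule: with 253 candidates and n = 400 the 1-SE rule is often degenerate
(intercept-only), and the minimum-deviance λ is the choice that the
"features with nonzero coefficients" framing implies.

The SMI enters selection alongside the 253 radiomics features, but the
**rad-score** is the coefficient-weighted sum of the selected *radiomics*
features only; the SMI then enters the combined model as its own covariate.
This keeps the two predictors separable (separate odds-ratio rows, a
two-variable VIF) and avoids counting muscle quantity twice. The combined
model is an ordinary two-covariate maximum-likelihood logistic fit;
perfect separation is detected and handled by a ridge-stabilized refit
(penalty 10⁻⁶) with a warning.

## Evaluation

AUC is the Mann–Whitney pair statistic; its 95% CI uses the DeLong
variance (a stratified bootstrap is available). Operating points use the
inclusive rule *positive iff score ≥ threshold* over all observed scores,
so reported sensitivities correspond to reachable classifications and the
waterfall partition at the Youden cutoff reproduces them exactly. Youden
ties break toward the smallest threshold (favoring sensitivity — the known
weakness of SMI-only models). Decision curves use
NB(p_t) = TP/N − (FP/N)·p_t/(1−p_t) on a default grid 0.01–0.99 (step
0.01); the treat-all reference crosses zero exactly at the prevalence.
Group comparisons follow baseline-table practice: Pearson chi-squared
without continuity correction for r×c counts (Fisher's exact when any
expected cell < 5), Student t / Mann-Whitney for two groups, one-way ANOVA
(raw or from summary statistics) for three.

## The synthetic phantom cohort

Each phantom is an axial abdomen proxy on a 512 × 512 grid (0.88 mm
pixels, five 5 mm slices): an elliptical fat-HU body (semi-axes
180 × 150 mm), a circular muscle ring (inner radius 60 mm — a
paraspinal/abdominal-wall proxy; only area and HU statistics matter
downstream), a central bone disk, and air at exactly −1000 HU outside the
body. Tissue HU are Normal: muscle 50 ± 12, fat −100 ± 20, bone 400 ± 80.

Muscle-ring voxels draw from the mixture
(1−f)·N(muscle) + f·N(fat), f the patient's fat-infiltration fraction
(Beta(2, 8); mean 0.20). By default the infiltrated voxels are selected by
thresholding a Gaussian-smoothed noise field (σ = 3 px), giving spatially
coherent fat streaks — texture features are sensitive to spatial
structure, and i.i.d. salt-and-pepper infiltration (available as
`infiltration = "iid"`) is a much weaker texture signal than real
intermuscular fat. The ring is sized so its *lean* area — what the HU
window recovers — divided by height² equals the patient's true SMI; the
contoured ROI includes the intramuscular fat, exactly as a real muscle
contour does. End-to-end, pipeline SMI recovers true SMI within 2%
(rasterization plus HU-tail leakage).

Covariates: 70% male; SMI Normal(49, 7) for males, Normal(41, 6) for
females, giving a pooled 46.6 ± 7.7 cm²/m², matching the published cohort
profile this generator emulates (46.8 ± 7.5); height 1.70/1.59 ± 0.06 m;
weight derived from BMI ~ Normal(23.2, 2.8). Extreme joint tails (height
> 1.90 m, SMI > 75, f > 0.45) are truncated so every phantom's muscle ring
fits inside the body ellipse.

Ground-truth toxicity follows
P = logit⁻¹(β0 + β1·z(−SMI) + β2·z(f)) with β1 = 0.8, β2 = 0.6 and
z-scores computed from the *analytic* cohort moments (so a patient's label
does not depend on who else was sampled). β0 = −1.0 was calibrated once,
by Monte-Carlo integration over the covariate model, to put the prevalence
at the 0.30 design target; the naive choice logit⁻¹ applied to −0.9 misses
that target (0.32) because averaging the inverse-logit over a unit-variance
linear predictor shrinks the mean probability toward ½.

What passing tests on phantoms do **not** show: the phantom has no organ
anatomy, no contrast enhancement, no scanner/reconstruction-kernel texture,
no partial-volume gradients at muscle boundaries, and its infiltration
field is statistically stationary. Recovery results certify the *pipeline*
(geometry, feature math, leakage-free modeling, evaluation), not the
clinical effect size, which only patient data can provide.

## Problem sizes and numerics

The recovery experiment used throughout (tests and the acceptance script)
is 570 phantoms — 400 training, 170 validation, the 7:3 study design at a
size where AUC standard errors are ~0.03 — which runs in a few minutes on
one CPU; texture-matrix accumulation is compiled (Rcpp), everything else
is vectorized R. Oracle checks run on ≤ 6 × 6 grids where exhaustive
enumeration is feasible. Monte-Carlo test tolerances are 3 standard errors
of the quantity under its design value. Seeds: one master cohort seed;
per-patient render seeds drawn from it (so phantoms re-render lazily and
order-independently); separate split and cross-validation seeds.

## Known limitations

* 2-D texture aggregation; no GLSZM/NGTDM families; no IBSI certification.
* The feature catalog is a reconstruction of the standard family members,
  not a certified list.
* Box-Cox clipping of out-of-range validation values is a pragmatic
  totality fix; heavy reliance on it would signal train/validation drift.
* The multivariate odds-ratio table does not do stepwise covariate
  selection; callers choose the adjustment set.
* Decision-curve confidence bands and calibration assessment are out of
  scope.
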