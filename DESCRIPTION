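Package: radsarc
Title: Skeletal-Muscle CT Radiomics for Treatment-Toxicity Risk Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for CT body-composition radiomics at the
    third lumbar vertebra (L3): Hounsfield-unit muscle segmentation and
    skeletal muscle index (SMI), a 253-feature radiomics engine (shape,
    first-order intensity, GLCM and GLRLM texture on the original image and
    four undecimated Haar wavelet subbands), LASSO-penalized logistic
    rad-score construction with cross-validation, combined SMI + rad-score
    risk models, and evaluation by ROC/AUC with DeLong confidence intervals,
    F1 score, Youden cutoffs and decision-curve analysis. Includes a
    synthetic CT-phantom cohort generator with known ground truth so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    grDevices,
    jsonlite,
    pROC,
    Rcpp,
    RNifti,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
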