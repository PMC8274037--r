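Package: mtbimeth
Title: Methylation-Based Outcome Prediction After Pediatric Mild Traumatic Brain Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for predicting four-month post-injury
    outcomes (post-concussive symptom burden, pediatric quality of life)
    from subacute saliva DNA methylation and clinical features. Provides
    beta-value quality control (detection-p masking, sample/probe filters,
    quantile normalization, imputation, ComBat batch adjustment,
    reference-based cell-type deconvolution, principal-component outlier
    removal), per-CpG mixed-effect association testing with a family random
    intercept, pathway-restricted independent component analysis with a
    consistency-based component count, L1-regularized support-vector
    regression with leave-one-out lambda tuning and significant-weight
    feature selection, a z-score rule for persistent post-concussion
    symptoms with ROC/AUC evaluation, and a synthetic-cohort generator that
    plants batch effects, cell mixtures, family structure, latent
    methylation components and component-outcome effects with a recoverable
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    stats,
    boot,
    Rcpp,
    utils,
    lme4,
    limma,
    sva,
    quadprog,
    clue,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
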