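Package: adcascade
Title: Data-Driven Causal Modelling of Alzheimer's Biomarker Cascades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers, calibrates and personalizes a sparse polynomial
    ordinary-differential-equation model of the Alzheimer's disease biomarker
    cascade (CSF amyloid-beta 1-42, CSF total tau, hippocampal volume ratio,
    ADAS-13 cognition) on a common disease-progression-score (DPS) time axis.
    Provides four-parameter sigmoid trajectory fitting and denoising, Lasso
    based recovery of the cascade model structure from smoothed trajectories,
    alternating nonlinear least-squares calibration of population weights
    jointly with per-subject linear DPS warps, variance-based (Sobol) global
    sensitivity analysis of the calibrated weights via Saltelli sampling on a
    Sobol low-discrepancy design, sensitivity-guided personalized refits with
    leave-last-visit-out prediction accuracy, and a synthetic ADNI-like
    longitudinal cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
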