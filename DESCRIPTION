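Package: symdim
Title: Leakage-Safe Multisite Prediction of Latent Depressive Symptom
    Dimension Change
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting treatment-related change along latent
    depressive-symptom dimensions (somatic disturbances, core mood and
    anhedonia, insomnia) of the 17-item Hamilton Depression Rating Scale
    from clinical, demographic, and regional brain-volume-change features
    pooled across acquisition sites. Implements fold-contained confound
    residualization, empirical-Bayes location/scale batch harmonization
    with train/apply parameter transfer, repeated site-stratified
    cross-validation with a bagged regression-tree ensemble, permutation
    significance tests, permutation importance (percent increase in mean
    squared error), median-conditioned partial dependence profiles, and
    leave-one-site-out validation with pseudo-site harmonization. A
    synthetic multisite cohort generator with planted effects supports
    parameter-recovery and leakage audits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
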