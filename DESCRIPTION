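Package: mammotex
Title: Mammographic Texture Analysis and Matched Case-Control Risk Evaluation
Version: 0.1.0
Authors@R:
    person("PROCAS", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automated texture analysis of raw ("for processing")
    digital mammograms: breast segmentation, percentile windowing,
    multi-resolution bicubic image pyramids, and grey-level texture feature
    families (GLCM, NGTDM, run-length, size-zone, histogram and form
    features). Includes feature selection by correlation screening and
    L1-penalised logistic regression with leave-one-out cross-validation
    and the one-standard-error rule, a published three-feature sum-average
    risk score, evaluation statistics for matched case-control designs
    (conditional logistic regression, likelihood-ratio tests, standardized
    odds ratios, the matched concordance index with bootstrap confidence
    intervals), and synthetic phantom/cohort generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
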