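Package: ddmr
Title: Indirect Reference Intervals from Routine Laboratory Data via
    Differential Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates sex- and age-stratified reference intervals for clinical
    analytes from routine (mixed inpatient) laboratory data using the
    Differential Distribution Method: per-ICD-10-category significance testing
    of coded subpopulations against the stratum's global distribution with
    Storey-Tibshirani false discovery rate control, removal of significantly
    deviating groups, optional comorbidity-aware pooling of codes by
    co-occurrence embeddings and cosine-distance agglomerative clustering, and
    iterative Gaussian-mode reference interval inference with percentile
    confidence intervals and distribution-comparison verdicts. Includes a
    synthetic mixed-population generator with closed-form ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
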