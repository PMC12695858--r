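Package: srssignal
Title: Disproportionality Signal Detection and Onset Modelling for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pharmacovigilance analysis of spontaneous
    reporting system (SRS) databases such as FAERS and JADER: readers for
    both table dialects with case-version deduplication and
    missing-data handling, 2x2 disproportionality statistics (reporting
    odds ratio and the Bayesian Confidence Propagation Neural Network
    information component) with the usual signal criteria, Weibull
    probability-plot characterisation of time-to-onset with
    failure-pattern classification, and age- and sex-adjusted reporting
    odds ratios via logistic regression with collinearity diagnostics.
    Includes a synthetic SRS generator with known ground truth so every
    stage of the pipeline can be validated without access to the real
    databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    fitdistrplus,
    car,
    jsonlite
Config/testthat/edition: 3
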