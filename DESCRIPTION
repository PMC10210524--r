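Package: snroc
Title: Diagnostic Accuracy Corrections for Biomarker Measurement Error
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Corrects diagnostic accuracy measures (AUC, sensitivity,
    specificity) for attenuation caused by biomarker assay measurement
    error.  Implements the classical probit-scale correction for
    attenuation under binormal models, a skew-normal biomarker correction
    estimator for skewed markers, moment-based identification of error
    variances from two assay measures of the same biomarker (including
    linearly calibrated assays and replicate designs), optimal linear
    combination of noisy assays, stratified bootstrap inference, and a
    Monte-Carlo simulation harness for case-control biomarker studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
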