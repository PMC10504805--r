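Package: edentrisk
Title: Development and Validation of a 12-Year Incident Edentulism Risk Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for developing and validating a logistic
    risk-prediction model of 12-year incident edentulism (complete tooth
    loss) among older adults, mirroring the split-sample workflow used with
    Health and Retirement Study (HRS) cohort data: eligibility filtering and
    complete-case exclusion accounting, indicator coding of demographic and
    behavioural predictors, enumeration of 32 candidate models (a fixed core
    of six variables plus all subsets of five candidates), Monte Carlo
    cross-validation with model selection by mean validation AUC and a
    parsimony rule, recalibration on the selection set, percentile-bootstrap
    confidence intervals for the test-set AUC, prevalence-cutpoint
    classification metrics, and Table-1 style cohort descriptives. Because
    the HRS micro-data are access-restricted, the package includes a
    synthetic cohort generator that reproduces the published marginal
    distributions and outcome model, so every stage of the pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
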