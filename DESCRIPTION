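Package: ewaspipe
Title: Quality Control and Survey-Weighted Regression for Environment-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quality-control-to-analysis workflow for environment-wide
    association studies (EWAS) of mixed-type exposure data. Provides typed
    tabular data management with an audit trail, reproducible variable-level
    QC filters (unique-value type inference, minimum sample size, per-category
    counts, percent-zero), design-based regression of each exposure against an
    outcome under stratified, clustered, weighted sampling with Taylor-series
    linearization variance, likelihood-ratio and design-based Wald tests for
    categorical predictors, Bonferroni and Benjamini-Hochberg multiple-testing
    correction, category-grouped Manhattan plots, and a synthetic survey-data
    generator with a ground-truth sidecar for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
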