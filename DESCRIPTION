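Package: fairpost
Title: Post-Processing Bias Mitigation Benchmarks for Clinical Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for empirically comparing post-processing debiasing
    methods for binary clinical risk classifiers. Provides a synthetic
    biased-data generator (class-conditional bivariate Gaussians with a
    protected attribute derived from the first feature), stratified
    resampling to target unprivileged-group rates under class balance,
    group-fairness metrics (equal opportunity and equalized odds
    differences), seven post-processing debiasing algorithms behind a
    single fit/apply decision-policy interface, a mutation-based
    fairness-performance trade-off baseline with region classification
    (including a configurable healthcare performance-retention line), and
    a cross-validated benchmark harness producing change tables and
    untreated-attribute impact summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
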