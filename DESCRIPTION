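Package: dews
Title: Dynamic Early Warning Scores for Ward Vital-Sign Time Series
Version: 0.1.0
Authors@R: person("DEWS", "Maintainers", email = "dews@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating dynamic early warning scores
    (DEWS) from time-stamped ward observation sets. Implements NEWS-2
    aggregate scoring with both oxygen-saturation scales, time-series
    feature engineering (hinge splits of U-shaped vitals, inspired-oxygen
    ordinal encoding, differences, rolling statistics and slope-trajectory
    categories), L2-regularised logistic scoring models for deterioration
    outcomes at 24-hour and 4-hour horizons with episode-grouped stratified
    cross-validation, ROC and precision-recall evaluation with bootstrap
    confidence intervals, matched-threshold score comparison, event-window
    detection cross-tabulation, ROC-comparison sample-size planning, and a
    seeded synthetic ward-cohort generator with trend-bearing
    deteriorations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
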