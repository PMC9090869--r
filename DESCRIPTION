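Package: actisleep
Title: Accelerometer-Based Sleep Parameter Estimation for Complex Survey Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end pipeline for minute-level wrist-accelerometer sleep
    epidemiology in the style of the NHANES 2011-2014 24-hour accelerometry
    releases. Implements minute-level quality masking and wear-day validity
    rules, deterministic and zero-inflated imputation of long missing
    intervals, an unsupervised two-state Gaussian hidden Markov model on
    log-transformed MIMS activity for per-minute sleep/wake inference,
    noon-to-noon sleep-period-time (SPT) window detection with wake-bout
    accounting (clock time of sleep onset on a continuous 12-36 h scale,
    sleep duration, sleep efficiency), and design-based estimation for
    stratified two-PSU-per-stratum surveys: Taylor-linearized means and
    quantiles, survey-weighted quartic-age trend regression with sex and
    race interactions, and survey-weighted proportional-odds regression on
    sleep-efficiency quartiles. Includes a synthetic cohort generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    arrow,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
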