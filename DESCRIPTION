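Package: abpmaf
Title: Autonomic Failure Screening from 24-Hour Ambulatory Blood Pressure Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive autonomic-dysfunction markers from 24-hour
    ambulatory blood pressure monitoring (ABPM) in Parkinson's disease and to
    evaluate them as a screening test for cardiovascular autonomic failure.
    Implements reading and validation of timestamped ABPM recordings with
    diary events, extraction of circadian blood-pressure parameters (day/night
    means and standard deviations, blood-pressure loads, reverse dipping,
    duration-weighted blood-pressure variability, postprandial hypotension,
    morning hypotensive episodes and awakening hypotension), reference
    labelling from cardiovascular autonomic reflex testing (orthostatic
    hypotension, supine hypertension, composite-score diagnosis), a two-class
    linear discriminant classifier written from first principles, full
    diagnostic-accuracy statistics (contingency metrics with exact confidence
    intervals, empirical ROC curves with Youden cut-points, odds ratios,
    logistic regression), and a seeded synthetic-cohort generator calibrated
    to published group statistics for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
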