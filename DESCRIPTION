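Package: icebound
Title: Bioenergetic Trade-Off Analysis for Overwintering Juvenile Trout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for two-strain, two-winter-duration whole-lake
    experiments on juvenile rainbow trout. Converts temperature-logger series
    into ice-cover durations and growing-degree-day standardizations, computes
    mass-specific growth rates per calendar day and per degree day, estimates
    abundance and survival with the Chapman-corrected Petersen mark-recapture
    estimator and activity-based catchability from fyke-net effort, models
    overwinter starvation thresholds from the mass-respiration allometry and
    winter lipid depletion, fits the log-log mass-lipid allometry, and tests
    strain, environment, and strain-by-environment effects with split-plot
    mixed ANOVA using classical denominator degrees of freedom. A seeded
    synthetic-data generator reproduces the stocking design so the full
    pipeline runs without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    withr,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
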