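Package: briskpilot
Title: Pilot-Trial Analytics and Health Economics for a Brisk-Walking
    Intervention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis toolkit for a two-arm pilot randomised
    controlled trial of an app-based walking intervention in adults living
    with and beyond cancer. Generates synthetic trial inputs with known
    ground truth (participant-flow ledgers, cohort tables, event-level
    thigh-accelerometer traces and wear logs); derives daily and weekly
    brisk-walking outcomes (cadence above 100 steps/min) from event-level
    activity records with valid-day filtering and sleep/wake delineation;
    computes CONSORT-style feasibility and fidelity metrics; reproduces an
    unequal-variance (Welch/Satterthwaite) phase-III sample-size
    calculation with simulation-based power verification; and runs a
    lifetime three-state Markov cohort cost-effectiveness model linking
    MET-hour activity changes to cancer and other-cause mortality, with
    probabilistic sensitivity analysis, cost-effectiveness acceptability
    curves and expected-value-of-information analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    mgcv,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
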