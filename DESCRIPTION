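Package: uoaki
Title: Standardized Hourly Urine Output and Oliguric AKI Staging for ICU Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Converts raw intensive-care urine-output charting (volumes charted at
    irregular times from multiple collection sources) into standardized
    hourly-adjusted urine output rates, stages oliguric acute kidney injury under
    both customary KDIGO urine-output interpretations (running-window mean and
    consecutive-hour), and runs the downstream cohort analysis: peak staging over
    the first ICU days, unadjusted and marginal adjusted 30-day mortality odds
    ratios, and Kaplan-Meier survival comparison. Includes a seeded synthetic
    cohort generator with analytic ground truth so every pipeline stage is
    testable without credentialed ICU databases.
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
    zoo,
    survival,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
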