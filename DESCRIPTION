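Package: somnophone
Title: Smartphone-Based Passive Sleep Estimation and Sleep-Quality Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates nightly sleep duration from raw smartphone sensor
    streams (tri-axial accelerometer plus screen/lock device-state events)
    by thresholding accelerometer jerk magnitudes with Otsu's method,
    fusing the result with device on-events, bridging gaps of missing data
    by their neighbouring activity states, and filtering 24-hour windows
    by 5-second-bin data coverage. Aligns the passive estimates with daily
    sleep surveys and weekly Pittsburgh Sleep Quality Index (PSQI) scores,
    and models PSQI with random-intercept mixed linear regression and a
    leave-one-out cross-validated linear predictor. Includes a synthetic
    cohort generator that emulates the statistical structure of a
    month-long college-student digital-phenotyping study, so the whole
    pipeline is testable without access to sensitive participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
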