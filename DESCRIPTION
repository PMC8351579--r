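Package: surveypower
Title: Power Analysis for Presence-Absence Acoustic Surveys of Chorusing Anurans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the detection power of human audio surveys
    from interval-binned automated-recorder data. Continuous recordings are
    summarised as 5-minute detection/non-detection intervals; Monte-Carlo
    resampling of surveyable intervals under alternative scheduling scenarios
    yields detection-probability distributions by survey duration; the
    minimum number of surveys needed for a chosen confidence in absence is
    computed from the cumulative detection-probability formula; and a grid
    search over environmental thresholds (temperature, 24-h precipitation,
    24-h barometric-pressure change, and others) identifies scheduling rules
    that concentrate survey effort on high-activity nights. A synthetic-data
    module generates hourly weather, moon illumination, and chorus-activity
    interval tables with realistic seasonal and nightly structure so the full
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    lubridate,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
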