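Package: rhinomove
Title: Mesoscale Movement and Recursion Analysis for Gappy Megaherbivore Telemetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing recursive movement in irregular GPS telemetry at
    daily, biweekly and annual scales, motivated by black rhinoceros relocation
    data. Standardises gappy fixes to four diel anchors (dawn, midday, dusk,
    midnight) and computes time-standardised displacement rates; builds 1 km
    time-use grids over 16-day compositing intervals with number-of-separate-visits
    (nsv) and mean-locations-per-visit (mlsv) statistics under an inter-visit gap
    rule; links grids to greenness (NDVI) rasters and characterises the hill-shaped
    recursion-greenness relationship; measures annual time-to-return distributions
    at a 7-day inter-visit gap with waterhole-cell exclusion; and estimates k-LoCoH
    home-range isopleths with a log-area versus greenness random-intercept model.
    Includes a seeded generator of rhino-like trajectories, waterholes and
    greenness landscapes so every stage is testable without sensitive relocations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
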