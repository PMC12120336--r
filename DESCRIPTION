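Package: tagtrack
Title: Combined Acoustic-Telemetry and Archival-Tag Analysis for Coastal Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing double-tagged fish (acoustic transmitters
    plus archival depth/temperature tags) in coastal seas: quality control
    and filtering of acoustic detections, post-tagging survival
    classification, station residency statistics, listening-effort
    normalisation, seasonal movement graphs, and a gridded hidden Markov
    geolocation model that fuses depth and temperature records with
    acoustic detections, including diffusion estimation and a
    track-sensitivity diagnostic. A synthetic-data module generates
    complete scenarios (environment, tracks, sensor series, detections)
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    lubridate,
    ggplot2,
    igraph,
    yaml,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
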