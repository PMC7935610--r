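Package: cascadr
Title: Disruption-Cascade Detection in Irregular Event Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for timestamped event streams such as surgical
    flow disruptions. Loads tabular event data, derives per-case relative time,
    regularizes irregular event times into fixed-width count series, detects
    change-in-mean changepoints (AMOC, binary segmentation, exact optimal
    partitioning, and PELT, implemented from first principles), identifies
    cascades as sustained high-rate periods, attributes cascade triggers,
    and computes event-type enrichment probabilities. Includes a seeded
    piecewise-constant-rate point-process simulator with planted cascades so
    every stage is testable without external data, and ggplot2-based stem-plot
    rendering with faceting, pagination, and changepoint/cascade overlays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
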