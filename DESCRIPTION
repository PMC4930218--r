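Package: gearsense
Title: Gear-Specific Fishing-Activity Detection from AIS Vessel Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects fishing activity in satellite-AIS vessel trajectories
    with three gear-specific methods: a two-state hidden Markov model on
    vessel speed for trawlers, a data-mining pipeline for longliners
    (time regularization, Lavielle minimum-contrast segmentation,
    straightness classification, first-passage-time variance filtering and
    kernel utilization-distribution correction), and a multi-layer
    daylight/offshore/speed filter for purse seiners.  Includes track
    readers and writers, solar day/night flagging, haversine
    distance-to-shore computation, a synthetic labeled-track simulator per
    gear type, confusion/effort evaluation metrics and a Monte Carlo
    sliding-window testing harness, plus a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
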