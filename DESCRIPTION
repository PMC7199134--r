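Package: actirhythm
Title: Activity, Sleep and Circadian Rhythm Patterns from Raw Wrist Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end framework for raw wrist-worn sensor data (triaxial
    acceleration, ambient light, wrist temperature): calibration, resampling,
    non-wear detection, per-minute activity summaries, a light-assisted
    three-rule sleep/awakening detector, a registry of 50 activity, sleep and
    circadian rhythm patterns (M10/L5/RA, interday stability, intraday
    variability, cosinor rhythmometry, composite multiscale entropy,
    Teager-Kaiser energy, sleep fragmentation metrics), cohort-level group
    statistics, actogram-style visualisations, and a seeded synthetic
    recording generator with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Rcpp,
    yaml,
    jsonlite,
    ggplot2,
    withr,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
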