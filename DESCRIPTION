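Package: casparkle
Title: Simulation and Detection of Calcium Sparkles in Ratiometric
    Two-Photon Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-channel (calcium-sensitive green /
    calcium-insensitive red) time-lapse fluorescence movies of motile T
    cells imaged by two-photon microscopy. Provides a seeded synthetic
    movie generator with ground truth (spherical cells with nuclear
    indicator exclusion, persistent-random-walk motility, Hill-type green
    fluorescence, autofluorescent objects, Poisson and Gaussian noise); the
    ratiometric preprocessing chain (median filtering, maximum-intensity
    z-projection, Bernsen autofluorescence masking with dilation, scaled
    red-channel subtraction, temporal-mean subtraction); detection and
    classification of subcellular "sparkles" and cell-wide transients by
    standard-deviation and area thresholds with coincidence exclusion and
    analytic background-event statistics; four-parameter Hill calibration
    of the indicator against a fura-2 reference; and front/back subcellular
    signal comparison with an exact Mann-Whitney test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
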