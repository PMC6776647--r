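Package: whalescan
Title: Two-Stage Detection and Counting of Whales in Very High
    Resolution Ocean Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Survey pipeline for counting whales in large very
    high resolution (VHR) RGB ocean scenes. A scene is tiled into 71 x 71 m
    grid cells; a three-class presence classifier (whale, ship, water +
    submerged rocks) filters the cells, and a detector localises and counts
    individual whales in the cells that pass, so that the expensive
    detection stage runs only where whales are likely. Includes a seeded
    generator of annotated synthetic ocean scenes (six whale postures,
    ships, submerged rocks with foam, wave texture, sun glint), the
    training-time augmentation recipe with bounding-box transforms,
    CPU-trainable default models with an RMSProp schedule, IoU-based
    detection matching, posture-stratified detectability analysis,
    stratified k-fold evaluation and a detector-alone baseline comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    rlang,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, Visualization
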