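Package: trapcount
Title: Sliding-Window Detection and Counting of Insects on Sticky-Trap Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated counting of small insects (such as the black pine bast
    scale) on large pheromone sticky-trap photographs. Implements overlap-aware
    sliding-window tiling of large images, a pluggable detector interface with
    a reference intensity-blob detector and a configurable noisy oracle,
    duplicate elimination by interior-edge box removal and global non-maximum
    suppression, per-trap counting, average-precision evaluation at
    configurable IoU thresholds, counting-error evaluation, and detection
    score-threshold calibration on held-out traps. Ships a seeded synthetic
    sticky-trap image generator so the whole pipeline is testable end-to-end
    without trained detector weights. Annotations are read and written in
    Pascal-VOC-style XML and COCO-style JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
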