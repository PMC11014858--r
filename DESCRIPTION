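Package: beamwalkr
Title: Automated Slip Detection and Posture Analysis for the Mouse Beamwalk Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns markerless pose-estimation output (DeepLabCut-style
    tracking CSV files) of mice crossing an elevated beam into quantitative
    motor-coordination readouts. Reads and conditions per-frame x/y/likelihood
    keypoint tables, reconstructs the beam top line and pixel calibration from
    tracked landmarks, restricts analysis to the marked trial span, excludes
    stationary frames, expresses body-part height as a percentage of beam
    height, detects and classifies below-beam paw excursions as minor or major
    slips, and computes tail-base angles, body area and trial timing metrics.
    Group-level comparisons use two-tailed Mann-Whitney U tests with
    Bonferroni-Holm correction, and kernel density summaries describe
    body-position distributions. A synthetic trajectory simulator generates
    tracking tables with known ground truth (slip events, body offsets,
    stationary bouts, likelihood dropouts) so the whole pipeline can be
    validated without recorded videos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
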