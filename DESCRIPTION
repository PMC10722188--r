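Package: beamgait
Title: Posture and Gait Analysis for Mice Traversing a Balance Beam
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for markerless pose-estimation output of
    mice walking a balance beam. Reads DeepLabCut-style tracking tables,
    merges opposed 90-degree camera views or reconstructs 3D postures from
    45-degree stereo pairs via line-based autocalibration and triangulation,
    computes per-frame speed vectors, extracts a standard walk cycle (SWC)
    by template-matched cycle segmentation and correlation-weighted
    averaging, generates drift-free synthetic walk animations, and abstracts
    gait events and anomalies with the variance-of-correlation (VoC)
    statistic. Ships a ground-truthed synthetic gait simulator so the whole
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
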