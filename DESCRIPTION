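Package: tardigait
Title: Quantification of Octopedal Locomotion and Interleg Coordination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying walking behavior of tardigrades and other
    slow octopedal walkers from video-derived tracks and per-leg step timing.
    Detects the animal in each frame, computes windowed speed and heading,
    calls stops and turns, and segments sustained walking bouts; converts
    per-leg swing/stance onset series into stride kinematics (stance, swing,
    duty factor, step period, stride length and speed); classifies per-frame
    interleg coordination patterns (pentapod, tetrapod, tripod and rear-leg
    variants), measures ipsilateral and contralateral phase offsets,
    coordination consistency and strength scores, metachronal lag and its
    left-right symmetry; partitions strides by speed and compares groups of
    animals with test selection, centered log-ratio transforms for
    compositions and Benjamini-Yekutieli false discovery rate control. A
    fully parameterized synthetic walker generator provides ground-truthed
    leg event timelines, centroid paths and rasterized frames for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
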