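Package: ambitus
Title: Reward-Based Corridor-Maze Scoring, Behavioral Statistics, and
    D2-Receptor Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for reward-based behavioral pharmacology
    experiments in the Ambitus corridor maze. Scores millisecond-resolution
    beam-break event streams into eleven locomotion, exploration, attention
    and memory parameters; normalizes them as phase-wise z-scores with
    impairment-direction inversion; and runs the associated statistical
    battery (one-way and mixed repeated-measures ANOVA with
    Greenhouse-Geisser correction, Fisher's LSD post hoc, pooled t-tests,
    mean +/- 2 SD outlier exclusion). Also fits one-site saturation
    radioligand-binding curves (Bmax/Kd), quantifies western-blot
    densitometry with beta-actin normalization, and performs fluid-intake
    drug-dose accounting. Includes an agent-based simulator of rats in the
    apparatus and synthetic assay generators so the full pipeline can be
    exercised and calibrated without animal data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    car,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
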