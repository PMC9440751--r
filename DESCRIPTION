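Package: climbflight
Title: Stereo Videogrammetry and Wingbeat Analysis of Climbing Butterfly Flight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying climbing flapping flight from multi-camera
    high-speed video: direct linear transformation (DLT) camera calibration and
    stereo triangulation, Kalman smoothing of 3D body trajectories, wingbeat
    segmentation and per-wingbeat climb-performance metrics, stroke-plane wing
    Euler angles with blade-element wing speed and angle-of-attack estimation,
    a weight-normalized aerodynamic thrust model for climbing flight, and the
    accompanying statistical layer (sequential ANOVA, MANOVA via Wilks' lambda,
    phylogenetic ANOVA by Brownian-motion simulation on a species tree, linear
    regressions, correlations and rank-sum tests). Includes a ground-truthed
    synthetic flight and cohort generator so the full pipeline can be exercised
    and validated without video data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
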