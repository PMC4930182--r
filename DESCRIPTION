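Package: fmscore
Title: Automated Fugl-Meyer Upper-Extremity Scoring from Skeletal Motion Capture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring the upper-extremity motor section of the
    Fugl-Meyer Assessment (FMA) from depth-camera skeletal joint
    trajectories. Provides readers and writers for 31-variable joint
    recordings, preprocessing (side mirroring, motion clipping, pose
    normalization), kinematic feature extraction (joint angles, joint
    distances, range/variance summaries), the dimensionless normalized-jerk
    movement-smoothness statistic, per-item score prediction with PCA
    dimensionality reduction and a shared neural-network classifier under
    stratified cross-validation with minority oversampling, cohort-level
    statistics (score correlations, paired smoothness comparison,
    Brunnstrom-stage correlation), and a synthetic minimum-jerk motion
    generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    readxl,
    withr,
    yaml
Config/testthat/edition: 3
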