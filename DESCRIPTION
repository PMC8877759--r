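Package: curlfatigue
Title: Similarity-Weighted Personalization for Wrist-IMU Biceps Fatigue
    Detection
Version: 0.1.0
Authors@R:
    person("curlfatigue", "maintainers", email = "curlfatigue@example.org",
           role = c("aut", "cre"))
Description: Detects biceps-muscle fatigue in dumbbell concentration curls
    from a wrist-worn 50 Hz inertial measurement unit (3-axis accelerometer
    and gyroscope). Provides trough-to-trough repetition segmentation, Borg
    RPE labeling reconciled against heart rate, derived channels (total
    acceleration, exerted force, complementary-filter yaw), eleven
    hand-crafted features per repetition across nine channels,
    Manhattan-distance/exponential similarity scoring of a test subject
    against a crowd (physical, signal, and alpha/beta-blended total
    similarity), similarity-weighted AdaBoost classifiers (decision-tree and
    neural-network base learners implemented in-package), and the full
    evaluation protocol: leave-one-subject-out cross-validation, gamma and
    alpha/beta sweeps, and test-subject data-budget curves. A seeded
    synthetic cohort generator emulates the 25-subject concentration-curl
    protocol so the entire pipeline is exercisable without any downloads.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
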