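Package: remotegaze
Title: Behavioral Segmentation and Gaze-Tuning Analysis for Avian Hippocampal Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analyzing head-saccade behavior and hippocampal neural
    activity in freely moving birds performing a discrete visual-search task.
    Segments 300-Hz head-tracking traces into saccades, fixations, dashes and
    feeding bouts with a Gaussian-observation hidden Markov model and kinematic
    endpoint refinement; computes gaze rays and angular distances to task sites
    from head pose and per-eye calibrations; quantifies place and gaze tuning
    with an information statistic and shuffle null, a Poisson lasso GLM over a
    Gaussian angular-distance basis, saccade-aligned biphasic response
    analysis, and waveform/phase-based cell-type classification. Includes a
    ground-truthed synthetic-session generator (head pose, closed-loop task
    events, inhomogeneous-Poisson spike trains) for validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    mclust,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
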