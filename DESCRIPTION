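Package: mitotrack
Title: Tracking and Motion-State Analysis of Axonal Mitochondria in 4-D
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("MitoTrack", "Developers", email = "mitotrack@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying axonal mitochondrial transport from 4-D
    (xyz-t) fluorescence time-lapse stacks. Detects fluorescently labelled
    mitochondria via multi-scale Haar-like particle enhancement,
    feature-preserving non-local-means denoising and marker-controlled
    watershed segmentation; links detections into 3-D trajectories with an
    interacting-multiple-model (IMM) Kalman tracker; and classifies each
    trajectory timepoint into stationary, dynamic-pause, anterograde or
    retrograde motion states by decomposing windowed displacement into
    sustained and transient velocity components. Includes a synthetic-data
    simulator (four-state motor tug-of-war motion model, Gaussian PSF
    rendering, shot noise, photobleaching), kymograph construction,
    speed-distribution fitting and intersection-based threshold estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
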