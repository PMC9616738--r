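Package: pose2thal
Title: Robust 3D Pose Reconstruction and Neural-Behavioural Coupling in
    Freely Moving Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to link freely-moving rodent posture and movement to
    single-unit spiking activity. Provides a statistical shape model of the
    11-landmark mouse body (generalized Procrustes alignment plus
    probabilistic PCA), multi-camera triangulation and robust per-frame pose
    fitting with chi-square outlier rejection and model-based in-fill,
    extraction of 14 behavioural state variables (postures, their temporal
    derivatives, locomotion and overall motion), and a coupling suite for
    spike trains: epoch-permutation cross-correlograms, magnitude-squared
    coherence with shift controls, bias-corrected mutual information
    (quadratic extrapolation), gradient-boosted encoding/decoding models,
    dark/light tuning-stability statistics, and look-up/look-down unit
    classification by leading-eigenvector community detection. A synthetic
    session generator with ground-truth bookkeeping supports download-free
    testing and parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
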