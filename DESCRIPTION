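Package: craniomorph
Title: Landmark-Based Craniofacial Morphometrics: EDMA, Procrustes and
    Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical shape analysis of 3D anatomical landmark data as
    used in mouse craniofacial phenotyping. Implements Euclidean Distance
    Matrix Analysis (EDMA): form and shape difference matrices of relative
    Euclidean distances (RED), bootstrap omnibus significance testing with
    per-distance confidence intervals, and influence-landmark detection.
    Also provides Generalized Procrustes superimposition with shape PCA,
    Procrustes-distance permutation tests between groups, an integrative
    distance-feature PCA across several mouse models, small-sample
    expression and cell-proliferation statistics, and a synthetic
    landmark-cohort generator with localized regional genotype effects for
    calibration and power studies. Includes TPS and CSV landmark file I/O
    and a config-driven study pipeline.
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
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
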