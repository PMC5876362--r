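Package: neuroweight
Title: Neurally-Weighted Machine Learning with fMRI-Derived Activity Weights
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a two-stage "neurally-weighted" learning paradigm for
    binary visual object classification. Stage one trains RBF-kernel support
    vector machines on per-stimulus fMRI voxel response amplitudes and
    calibrates their decision scores into probabilities (Platt scaling); the
    resulting per-stimulus activity weights are injected into a second-stage
    image classifier through an activity-weighted hinge loss, solved by a
    per-sample box-constrained SMO solver. Includes a seed-reproducible
    synthetic data generator (category-selective voxels, pixel-label maps,
    feature vectors), the clear-sample labeling rule, region-of-interest
    combination bookkeeping, the balanced-problem experiment harness, and a
    permutation analysis with Bonferroni correction that quantifies which
    regions of interest drive accuracy gains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
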