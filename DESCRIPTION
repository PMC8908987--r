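Package: noduleCAD
Title: Texture and Shape Descriptors with Autoencoder Fusion for Lung
    Nodule Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A computer-aided characterization toolkit for pulmonary
    nodules in chest CT. From a 40 mm volume of interest and a binary
    nodule segmentation it computes three appearance descriptors (a
    multi-view analytical local binary pattern, a fast 3D histogram of
    oriented gradients built on integral gradient volumes with
    platonic-solid direction binning, and a Markov-Gibbs random field
    Gibbs-energy histogram) and three shape descriptors (a multi-view
    peripheral sum curvature scale space, a spherical-harmonic
    reconstruction-error curve, and fundamental morphological features).
    Each descriptor feeds a stacked autoencoder with a softmax head; the
    per-descriptor malignancy probabilities are fused by a final network.
    A synthetic nodule phantom generator provides labelled benign and
    malignant test objects so the whole pipeline can be exercised without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    RNifti,
    pROC,
    matrixStats,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
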