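Package: dpet4d
Title: Temporally Regularized 4D Reconstruction of Dynamic PET Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nested maximum a posteriori (MAP) 4D reconstruction of dynamic
    positron emission tomography (dPET) data, in which a temporal kinetic
    model is fitted to every voxel time-activity curve inside the iterative
    reconstruction loop. Implements the spline-residue model (arterial input
    function convolved with cubic B-spline residue bases), the spectral model,
    adaptive-knot cubic B-splines and irreversible two- and three-tissue
    compartment models; Tikhonov temporal regularization with per-voxel
    generalized cross-validation; an edge-preserving Lange spatial prior via
    optimization transfer; a desk-scale tomographic simulator (strip-integral
    projector, Poisson noise, thoracic-like digital phantoms); and the
    image and parametric-map bias/noise metric suite used to compare the
    algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    splines,
    utils,
    Matrix,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    RNifti,
    yaml,
    optparse
Config/testthat/edition: 3
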