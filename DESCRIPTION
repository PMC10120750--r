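Package: cellwrap
Title: Surface-Guided Unwrapping and Topographic Analysis of 3D Cell Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bijective mapping of closed 3D cell-surface meshes and
    membrane-associated signals between five equivalent representations:
    Cartesian 3D, a smooth genus-0 reference obtained by conformalized mean
    curvature flow, the unit sphere (quasi-conformal and equiareal spherical
    parameterizations), a topographic 3D space built by normal propagation of
    the reference surface, and the equirectangular 2D plane. On top of the
    mappings the package provides distortion metrics (conformal error, area
    distortion, Chamfer and sliced Wasserstein distances), topography-guided
    unsupervised segmentation of surface protrusions (blebs, lamellipodia,
    filopodia), cell-volume decomposition into cortex and protrusions, and
    distortion-corrected dynamic quantification (bleb tracking, event
    alignment, ruffle speed and cross-correlation analyses), together with a
    synthetic phantom generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    mclust,
    EBImage,
    jsonlite,
    tiff,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
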