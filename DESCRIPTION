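Package: tomoseg
Title: Headless CNN Segmentation, Model Interactions and Particle Picking for Cryo-Electron Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A batch-oriented toolkit for semantic segmentation of
    cryo-electron tomography volumes. Trains compact 2D convolutional
    neural networks on sparse 64x64 box annotations, segments tomograms
    slice-wise with overlap-blended tiling, refines multi-feature
    predictions with a conditional mask algebra (colocalization and
    avoidance interactions with an interaction radius, plus pixel-wise
    model competition), converts segmentations to particle coordinates
    via a distance-transform watershed picking procedure, and exports
    thresholded segmentations as triangulated meshes. Reads and writes
    MRC2014 volumes, tab-separated and STAR particle coordinate files,
    and Wavefront OBJ meshes. Includes a synthetic phantom generator
    (vesicle membranes, carbon-film slab, membrane-bound platforms,
    granules, filaments) with per-feature ground truth for end-to-end
    testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
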