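Package: penyek
Title: Sticky-Pad Insect Image Pipeline with Distance-Map Transforms and
    Compact Convolutional Classifiers
Version: 0.1.0
Authors@R: person("PENYEK", "Maintainers", email = "penyek@example.org",
    role = c("aut", "cre"))
Description: Classifies imperfect (damaged or flattened) brown planthopper
    specimens against benign insects in sticky-pad trap images.  Provides a
    seeded synthetic scene generator, a binarization front end (median
    filtering, iterative two-threshold between-class-variance maximization,
    morphological cleanup, size filtering, patch extraction and Canny-based
    negative mining), the six binary image transforms used as classifier
    inputs (outline, hole filling, skeletonization, watershed separation,
    Voronoi tessellation lines and the exact Euclidean distance map), a
    compact convolutional network engine with seeded augmentation and
    hard-negative bootstrapping, hand-crafted texture/colour feature
    baselines with a random forest, and a stratified cross-validation
    evaluation harness.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
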