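Package: voxelmvpa
Title: Linear Classifiers and Kernel Conditioning Diagnostics for Voxel-Based Morphometry
Version: 0.1.0
Authors@R:
    person("Ramon", "Vega", email = "rvega@example.org", role = c("aut", "cre"))
Description: Tools for studying high-dimensional classification of gray-matter
    density maps as a linear ill-posed problem. Provides a seeded synthetic
    cohort generator for two-class voxel-based morphometry studies, template
    thresholding and voxel-wise standardization, linear (Gram) kernel
    construction with SVD-based conditioning diagnostics (singular values,
    numerical rank, condition numbers), three linear classifiers (a dual-form
    pseudo-inverse least-squares classifier, elastic-net regularized logistic
    regression, and a soft/hard-margin linear support vector machine on
    precomputed kernels), principal-component-space counterparts with
    incremental component selection, and experiment drivers over sample-size by
    dimension grids with fixed held-out test evaluation and 10-fold
    cross-validated hyperparameter search.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
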