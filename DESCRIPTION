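Package: neuroSegReg
Title: Brain MR Slice Segmentation and Time-Series Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-dimensional brain magnetic resonance image analysis:
    a combined Chan-Vese / support-vector-machine (C-SVM) tissue segmentation
    pipeline in which a two-phase level-set contour isolates brain tissue and a
    Gaussian-kernel SVM labels the interior as cerebrospinal fluid, gray matter
    and white matter from gray-level co-occurrence texture features; and a rigid
    registration pipeline for brain functional time series built on block
    matching with recursive similarity accumulation, boosted match-reliability
    weighting and weighted orthogonal-Procrustes transform recovery. Includes a
    seeded synthetic brain phantom generator (piecewise-constant tissues, smooth
    multiplicative bias field, additive noise, rigid motion series with ground
    truth), evaluation metrics (Dice, pixel accuracy, target registration
    error), readers and writers for NIfTI, PNG and TIFF, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    e1071,
    RNifti,
    png,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'chanvese.R'
    'csvm.R'
    'glcm.R'
    'io.R'
    'metrics.R'
    'neuroSegReg-package.R'
    'phantom.R'
    'registration.R'
    'transforms.R'
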