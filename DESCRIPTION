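Package: IsoSeg
Title: Infant Brain MRI Tissue Segmentation with a (2+1)D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Volumetric segmentation of infant brain MRI into
    cerebro-spinal fluid, gray matter and white matter at the isointense
    stage, when gray- and white-matter intensity distributions converge
    and voxelwise contrast alone cannot separate them. Implements
    percentile-landmark intensity standardization (piecewise-linear
    histogram alignment at the 25th/50th/75th percentiles), a
    four-level U-Net whose three-dimensional convolutions are factorized
    into in-plane (1x3x3) and across-slice (3x1x1) stages ((2+1)D
    convolution), a hybrid sparse cross-entropy plus soft-Dice training
    cost with ADAM optimization and best-model checkpointing,
    leave-one-out cross-validation, and the full confusion-matrix,
    sensitivity/precision/Dice/accuracy metric suite with cohort
    aggregation. A synthetic two-modality phantom cohort generator
    emulates the isointense regime so the whole pipeline is testable
    without access-restricted clinical data. Reads and writes NIfTI-1
    and Analyze 7.5 volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    oro.nifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'harness.R'
    'losses-metrics.R'
    'net21d.R'
    'phantom.R'
    'standardize.R'
    'volume-io.R'
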