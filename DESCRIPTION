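Package: cardioscar
Title: Regional Left-Ventricle Scar Detection from Cardiac CT Angiography
    via Latent-Space Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects septal and lateral left-ventricle scar from
    single-phase cardiac CT angiography short-axis slices using
    encoder-decoder neural networks with latent-space classification
    branches. Provides the full data-generation chain (three-step
    iterative-closest-point mesh registration, heart-coordinate
    short-axis slicing with mask rasterization, septal/lateral region
    labeling with exclusion filters), image preprocessing (zoom, crop,
    intensity normalisation), variational and U-Net style architectures
    with focal, reconstruction and Kullback-Leibler losses, a
    patient-stratified cross-validation training loop with ROC metrics,
    and a synthetic phantom generator so that every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    pROC,
    jsonlite,
    yaml,
    png,
    tiff,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'cardioscar-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'labeling.R'
    'preprocess.R'
    'nn_layers.R'
    'networks.R'
    'losses.R'
    'training.R'
    'desk.R'
    'dicom.R'
    'mesh.R'
    'phantom.R'
    'pipeline.R'
    'registration.R'
    'slicing.R'
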