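Package: polypseg
Title: Self-Supervised Colorectal Polyp Segmentation with Synthetic Lesion Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation-free segmentation of colorectal polyps in endoscopy
    frames under a one-class anomaly-detection paradigm. Provides a procedural
    simulator that composites realistic polyp-like lesions into polyp-free
    mucosa images (polar-harmonic contour masks, patch-, texture- and
    hybrid-content synthesis with iterative colour-distribution transfer and
    soft shadow blending), a memory-augmented convolutional encoder-decoder
    that segments lesions as feature-space deviations from stored normal
    prototypes, a focal-loss training loop, morphological post-processing, and
    an evaluation harness with IoU/Dice metrics, group-sampling protocols and
    paired t-tests. Includes seeded generators of mucosa-like fixture images
    and texture patches so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    EBImage,
    png,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'RcppExports.R'
    'colortransfer.R'
    'evaluation.R'
    'fixtures.R'
    'inference.R'
    'mask.R'
    'model.R'
    'nn-autograd.R'
    'polypseg-package.R'
    'simulate.R'
    'training.R'
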