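Package: spectmets
Title: Automated Bone-Metastasis Detection on Whole-Body SPECT Bone Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the automated diagnosis of bone metastasis from
    whole-body SPECT bone scintigraphy. Implements adaptive thoracic-region
    cropping driven by row-profile landmarks, geometric augmentation
    (mirror, translation, rotation) with optional min-max normalization,
    declarative builders for a family of convolutional classifiers
    (VGG, ResNet-34, DenseNet-121 variants) backed by a compact
    convolutional-network engine, and a full binary-diagnostic evaluation
    harness (confusion-matrix metrics, ROC/AUC, repeated runs). A synthetic
    phantom generator emulates whole-body bone scans with known ground truth
    so every stage is testable without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
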