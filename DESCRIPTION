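Package: ccfocus
Title: Two-Stage Detection of Fetal Corpus Callosum Agenesis in Paired-Plane Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage diagnostic framework for fetal corpus callosum (CC)
    assessment from paired sagittal/axial cranial ultrasound images:
    region-of-interest extraction with dynamic boundary expansion, followed by
    an anatomy-aware dual-stream convolutional classifier with cross-view
    sigmoid gating and a learned per-case view-weighting coefficient. Includes
    a seeded synthetic speckle-phantom generator emulating the relevant cranial
    anatomy (skull ellipse, falx, hypoechoic CC band, cavum septi pellucidi,
    ventricles), the preprocessing pipeline (homomorphic speckle filtering,
    affine canonicalization, aspect-preserving resize, elastic deformation /
    rotation / brightness augmentation, test-time augmentation), Grad-CAM++
    attribution with clinical intensity banding, confusion-matrix and AUC
    metrics, and a clinician-AI collaborative score-fusion harness. Networks
    are trained from scratch with an internal Rcpp-accelerated engine; no GPU
    or external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
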