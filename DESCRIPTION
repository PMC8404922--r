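Package: contrastgan
Title: Contrast-Aware Conditional GAN for MR Image Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for training and evaluating a progressive-growing
    Wasserstein GAN with gradient penalty whose generator is conditioned on
    MR acquisition parameters (repetition time, echo time, and imaging
    orientation) through a separately trained auxiliary classifier with an
    adaptive conditioning-loss weighting scheme. Includes a physics-based
    spin-echo phantom generator with DICOM fixture output, a DICOM header
    curation pipeline (filtering, central-slice selection, resizing,
    normalization, study-level splitting), conditioning-fidelity metrics,
    acquisition-parameter interpolation grids, and a bias-corrected visual
    Turing test harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
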