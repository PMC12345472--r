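Package: ovineid
Title: Age-Invariant Sheep Face Identification via Feature Decoupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual identification of sheep from face images across
    growth stages (1-12 months). Implements a squeeze-and-excitation
    residual feature extractor, an efficient channel/spatial attention
    block (ECBAM), nonlinear decoupling of an embedding into an age code
    and an age-purged identity code, and an adversarial kernel
    canonical-correlation module that decorrelates the two codes during
    multi-task training (CosFace identity loss, linear age regression,
    weighted joint objective). Ships a synthetic longitudinal face
    generator with independent identity and age factors, the full
    verification metric suite (precision, recall, F1, IoU, mAP at 0.5,
    accuracy, EER with FAR and FRR curves), per-age-group evaluation,
    decoupling leakage diagnostics, gradient-weighted saliency maps, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
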