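Package: occlnet
Title: Recurrent Network Models and Analyses for Occluded Object Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how sequential and recurrent computation
    helps visual recognition of occluded objects. Provides a synthetic
    generator of FashionMNIST-like object images and a compositor that
    builds two-object occlusion scenes with exact occlusion-level control;
    a declarative zoo of feedforward, recurrent (ConvLSTM) and top-down
    network architectures with a computational-depth metric; a trainer
    implementing log-uniform hyperparameter search, learning-rate halving
    on bad epochs and abort rules; explaining-away comparisons across
    tasks and prediction orders; hidden-state replacement perturbation
    experiments; a GAN-based reconstitution model performing iterative
    latent inference; representational-similarity analysis by linear
    mapping with an instance-variability noise ceiling; and quality
    control plus paired statistics for the accompanying psychophysics
    design. Networks are trained by a small built-in reverse-mode
    differentiation engine with compiled convolution kernels, so the
    whole pipeline runs at desk scale on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
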