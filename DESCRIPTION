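Package: octpipe
Title: Retinal OCT Classification with a Compact Convolutional Transformer
    and GAN-Based Class Balancing
Version: 0.1.0
Authors@R:
    person("OCT", "Pipeline Maintainers", email = "octpipe@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for four-class retinal optical
    coherence tomography (OCT) image classification (CNV, DME, drusen,
    normal). Provides a seeded synthetic OCT phantom generator for offline
    testing, the classical enhancement chain (white-border removal,
    morphological erosion, median filtering, alpha-beta correction), a deep
    convolutional generative adversarial network (DCGAN) for augmenting
    minority classes, a compact convolutional transformer classifier with
    sequence pooling and its ablation grid, image-quality metrics (PSNR,
    SSIM), and an evaluation harness with stratified splits, k-fold
    cross-validation, dataset-reduction curves and an eleven-metric
    confusion-matrix report. All neural-network layers are implemented in R
    with Rcpp kernels for the convolution hot paths, so the whole stack runs
    on a single CPU with no external deep-learning runtime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
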