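Package: weedadapt
Title: Adversarial Domain Adaptation for Crop-Weed Semantic Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised and few-shot supervised domain adaptation for
    pixel-wise crop-weed recognition in field imagery. Provides a
    ConvNext-style encoder-decoder segmentation network with auxiliary
    head, fully convolutional patch discriminators, entropy minimization
    with a Charbonnier penalty, adversarial feature alignment, a
    progressive augmentation scheduler (geometric, noise and collage
    categories), a seedable synthetic field-image generator with
    pixel-perfect masks, mean-IoU evaluation, and an ablation harness.
    All network layers and their gradients are implemented in the
    package, with compute kernels in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
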