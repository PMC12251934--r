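Package: vimsa
Title: Pupil-Center Detection with a Bidirectional State-Space Encoder and
    FFT-Accelerated Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes the pupil center in single-channel grayscale eye
    images with a Vision-Mamba-style detector: patch embedding with a
    learnable per-patch weight channel, a stacked bidirectional selective
    state-space encoder whose sequence mixer is multi-head self-attention
    evaluated through an outer-product/FFT decomposition of the two matrix
    products, and a weight-modulated global-average-pooling regression head.
    Includes a synthetic labeled eye-image generator (dark elliptical pupil,
    iris annulus, glints, occluders, illumination gradients), RMSE and
    detection-rate metrics, a seeded AdamW training loop with cosine
    learning-rate decay, and radix-2 FFT primitives with a naive-DFT oracle
    and operation-count accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
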