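Package: asunet
Title: Attention Squeeze U-Net for Skin Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compact encoder-decoder convolutional networks for dermoscopic
    skin lesion segmentation, built around the Attention Squeeze U-Net: fire
    and transposed-fire blocks, attention gates on the skip connections, and a
    parameter-efficient channel schedule. Includes the Focal Tversky training
    loss, Dice/Jaccard/Threshold-Jaccard/accuracy evaluation with per-lesion
    class reporting, a preprocessing and flip-augmentation pipeline for paired
    image/mask datasets, a seeded generator of synthetic dermoscopy fixtures
    (lesion blobs with hair, bubble, pen-mark and reflection artifacts), and a
    seeded CPU training loop with validation-based model selection. The network
    engine (convolutions, transposed convolutions, pooling, reverse-mode
    differentiation, Adam) is implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
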