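Package: fruitnet
Title: Improved MobileNetV2 Networks for Agricultural Product Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A self-contained implementation of an improved MobileNetV2
    convolutional network for classifying agricultural product images in the
    Fruit-360 class-per-folder convention. Stride-1 inverted-residual blocks are
    replaced by Res-Inception blocks that run parallel depthwise 3x3, 5x5 and
    7x7 kernels with a residual skip, and an efficient multi-scale attention
    (EMA) module with cross-spatial learning is inserted between consecutive
    bottleneck blocks. Includes forward and reverse-mode (backpropagation)
    computation for every layer, Adam training with cross-entropy loss,
    confusion-matrix based evaluation metrics, a class-per-folder image reader
    with stratified splitting, a seeded synthetic fixture generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
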