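Package: pestpyramid
Title: Joint Insect Pest Detection and Classification with Pyramid
    Features, Attention Fusion and Metaheuristic Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale implementation of a two-stage insect pest
    analysis pipeline for agricultural images: a feature-pyramid-network
    (FPN) detector with adaptive per-level gating localizes pests of
    varying size, and a multi-scale attention-fusion transformer feeding
    an adaptive LSTM classifies the detected crops.  Hidden-layer widths
    and learning rates of both stages are tuned by a gooseneck-barnacle
    population metaheuristic whose random number is replaced by a
    fitness-ratio term, minimizing 1/accuracy + 1/IoU.  Includes a
    reproducible synthetic pest-scene generator with COCO-style
    annotation I/O, a full detection/classification metric suite
    (accuracy, IoU/CSI, MCC, informedness, ROC, k-fold), and plotting,
    tidying and command-line interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    png,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
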