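Package: mayflyseg
Title: Mayfly-Optimized Multilevel Kapur Thresholding, Feature Fusion and
    BiLSTM Classification for Brain MRI Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-stage brain-tumor detection pipeline for 2-D grayscale
    images: multilevel Kapur entropy thresholding optimized with the mayfly
    swarm algorithm to segment a tumor region; histogram-of-oriented-gradients
    and pre-activation residual-network embeddings fused by entropy-based
    feature selection; and a bidirectional LSTM classifier trained with Adam.
    Includes a seeded generator of brain-like phantom images with ground-truth
    tumor masks and learnable class labels, segmentation quality metrics
    (Tanimoto and Dice overlap), exhaustive-search threshold oracles, and
    one-vs-rest classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    jpeg,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    tiff
VignetteBuilder: knitr
Config/testthat/edition: 3
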