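Package: jade
Title: Joint Alignment and Deep Embedding of Paired Spatial Transcriptomics Slices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Jointly learns a probabilistic spot-level alignment (a
    doubly-stochastic transport plan obtained from a learned cross-attention
    cost via Sinkhorn-Knopp normalization) and shared low-dimensional
    embeddings (one-layer graph convolutional autoencoders with a graph
    contrastive objective) for a pair of spatially resolved transcriptomics
    slices. Includes a coarse-to-fine hyperspot acceleration, downstream
    evaluation utilities (model-based clustering, adjusted Rand index, iLISI,
    alignment accuracy, domain marker tests), a synthetic paired-slice
    generator with known ground-truth correspondence, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Matrix,
    mclust,
    jsonlite,
    optparse,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
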