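Package: ambimark
Title: Ab Initio Marker Gene Selection for Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotation-free selection of cell-type-discriminative marker
    genes from gene-by-cell expression matrices. A gene is kept when its
    per-cell expression density, estimated with a Gaussian kernel, is
    multimodal, and when it forms reciprocally connected pairs with other
    genes in k-nearest-neighbour co-occurrence or mutual-exclusivity
    graphs built from a mean-thresholded binary expression matrix.
    Includes readers for dense and 10x-style matrix-market inputs,
    baseline selectors (highest mean expression, highest variance or
    binned dispersion), clustering-based evaluation with the adjusted
    Rand index, a mixed-population synthetic data generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
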