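Package: segatac
Title: Genome Segmentation of Single-Cell ATAC-seq with
    Dirichlet-Multinomial Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments the genome into cross-cell accessibility states from
    single-cell ATAC-seq fragment files using a hidden Markov model with
    Dirichlet-multinomial emissions.  Supports feature identification
    (selection of rare, informative foreground states from per-cell counts),
    regulatory-program identification (segmentation of cluster-collapsed
    pseudo-bulk tracks and state-cluster association scores), and downstream
    statistics: nearest-TSS gene-set enrichment, stationary-distribution
    state enrichment scores, marker-gene log-ratios, Shannon-entropy
    cell-type specificity, exact binomial composition tests, and
    classification of regions against an external chromatin-state
    annotation.  Includes a fully specified synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
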