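Package: etacpipe
Title: Single-Cell and Tissue-Restricted-Antigen Analysis of AIRE-Expressing Dendritic Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for characterizing extra-thymic AIRE-expressing
    dendritic cells from count matrices: single-cell quality control,
    pool-deconvolution size-factor normalization, highly-variable-gene detection
    by a squared-coefficient-of-variation trend with a chi-squared excess test,
    rank-correlation clustering with dynamic tree cutting, diffusion-map
    pseudotime with meta-stable states by exact one-dimensional k-means,
    empirical-Bayes moderated-t differential expression, and a
    tissue-restricted-antigen arm built on the tau tissue-specificity index over
    a tissue atlas, including bulk median-of-ratios normalization and
    hypergeometric count downsampling. A synthetic-data module generates every
    input class with known ground truth so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Rtsne,
    limma,
    scran,
    DESeq2
Config/testthat/edition: 3
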