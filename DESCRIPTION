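Package: ragnmf
Title: Driver Gene Prioritization by Robust Adaptive Graph-Regularized
    Non-Negative Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Prioritizes candidate cancer driver genes from a binary
    samples-by-genes somatic mutation matrix without requiring tumor
    subtype labels. Genes are embedded in a low-dimensional non-negative
    subspace by a graph-regularized non-negative matrix factorization in
    which two simplex-constrained diagonal weight matrices adaptively
    down-weight noisy genes and outlier samples. Learned coefficient
    vectors yield per-gene mutation scores, descending rankings, and
    subgroup assignments; candidate lists are evaluated against benchmark
    gene sets with upper-tail hypergeometric overlap tests. Includes
    readers and writers for MAF, mutation-matrix TSV and GMT formats, a
    synthetic heterogeneous-cohort generator with planted drivers for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mclust,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
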