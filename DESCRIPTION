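Package: isopath
Title: Joint Isoform Identification and Quantification from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies expressed transcript isoforms and estimates their
    RPKM expression levels from per-exon and splice-junction read counts,
    without requiring an annotated isoform catalogue. Candidate isoforms are
    enumerated as source-to-sink paths on a splice graph built from detected
    junctions; expression is estimated under a nonnegativity- and
    Lp-sparsity-constrained Poisson maximum-a-posteriori model whose full
    regularization path is computed with a generalized boosted-lasso
    coordinate algorithm; the final model is chosen by grouping path
    solutions by model size and sequential likelihood-ratio testing.
    Includes a read-count simulator for validation, evaluation metrics,
    ROC-based expression thresholding, known/novel classification against
    annotation, readers and writers for TopHat junction BED, UCSC knownGene
    and GTF, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
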