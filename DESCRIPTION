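Package: atlaswalk
Title: Reference-Based Consensus Cell-Type Annotation and Signature
    Scoring for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates single-cell RNA-seq data by Pearson correlation of
    each cell against reference atlas expression profiles, refines the
    per-cell assignments by an iterative walk over a shared-nearest-neighbor
    dendrogram in which each cluster receives the cell type with the maximal
    trimmed-mean correlation until the labeling is stable for a fixed number
    of consecutive cuts, and projects sketch labels to the full dataset.
    Downstream tools cover cell and gene quality-control filters, Wilcoxon
    rank-sum differential expression, preranked gene-set enrichment with
    leading-edge extraction, per-cell gene-signature scoring, and two-sample
    Kolmogorov-Smirnov comparison of score distributions between conditions.
    Includes a synthetic-data generator with ground-truth labels for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
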