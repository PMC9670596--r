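Package: igenrich
Title: Hierarchical Enrichment of Imprinted Genes in Single-Cell Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Over-representation and running-sum gene-set enrichment analysis of
    a tagged gene set (by default a curated list of murine imprinted genes with
    parental-origin annotations) among the upregulated genes of cell identity
    groups in single-cell RNA-seq data. Implements the full workflow: sparse
    matrix input, gene-presence filtering, counts-per-10k normalisation,
    one-sided Wilcoxon rank-sum marker detection with horizontal
    Benjamini-Hochberg correction, level-dependent upregulation criteria,
    one-sided Fisher's exact over-representation tests with an eligibility gate
    and Bonferroni correction, weighted running-sum GSEA with a gene-set
    permutation null, parental-origin split analyses, expression summaries, and
    a negative-binomial synthetic-data generator with planted effects for
    end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    methods,
    jsonlite,
    ggplot2,
    data.table
Suggests: testthat (>= 3.0.0), withr, patchwork
Config/testthat/edition: 3
RoxygenNote: 7.3.3
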