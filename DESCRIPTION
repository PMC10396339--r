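Package: crossatlas
Title: Cross-Species Single-Cell and Single-Nucleus Atlas Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative single-cell and single-nucleus
    transcriptomics across species pairs connected by one-to-one
    orthologs. Provides a synthetic two-species data generator with
    known ground truth, CellRanger-style Matrix Market input/output and
    a pre-mRNA GTF utility, per-cell quality control, single-species
    atlas construction (normalization, highly variable gene selection,
    PCA, shared-nearest-neighbor graphs, Louvain clustering, UMAP),
    Wilcoxon rank-sum marker detection, ortholog-restricted
    CCA/mutual-nearest-neighbor integration, species-normalized cluster
    composition matrices, representation-factor marker-overlap
    statistics with hypergeometric p-values, and bulk RNA-seq
    isolation-method concordance analysis (quantile normalization,
    Spearman correlation, log2 fold-change distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    irlba,
    RANN,
    uwot,
    limma,
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
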