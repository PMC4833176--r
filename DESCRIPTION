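Package: cnvphen
Title: CNV Gene Assignment, Mouse-Phenotype Enrichment and Brain
    Co-Expression Connectivity Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a pipeline linking rare copy-number variants (CNVs)
    to candidate disease mechanisms through mouse-knockout phenotypes and
    brain co-expression. Genes are assigned to CNVs under asymmetric rules
    (full span containment for copy-number gains; disruption of a coding
    exon in every transcript for losses), filtered against direction-matched
    common CNVs from a control cohort, and tested per phenotype-ontology
    term for hypergeometric enrichment under ancestor closure with FDR
    control (Storey q-values or Benjamini-Hochberg). A correlation-threshold
    co-expression network supports permutation tests of gene-set
    connectivity (within-set cohesion, set-to-set connectivity against a
    constrained background, and a comparative composite-background test)
    with empirical p-values (k+1)/(n+1). A synthetic-data module generates
    toy genomes, CNV cohorts with planted enrichment, closure-consistent
    ontology annotations and expression matrices with planted correlated
    modules, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
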