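Package: funbic
Title: Functionally Relevant Bicluster Discovery in Two-Class Tumor Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Isolates cancer-specific functional differences between two tumor
    classes of different tissue origin from bulk RNA-seq counts. Implements
    differential expression with normal-tissue DEG exclusion, ISA and
    plaid-model biclustering, Fisher-exact selection of cancer-specific
    biclusters, gene-ontology biological-process enrichment, a GO-tree
    childness score that selects biclusters whose enriched terms are child
    terms of the DEG-enriched terms, and a PCA-stratified Kaplan-Meier
    survival screen. Ships a synthetic-cohort generator with planted ground
    truth so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
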