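Package: cernet
Title: Competing Endogenous RNA Network Inference and Survival Screening
    for Bulk Tumour Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for lncRNA-miRNA-mRNA (ceRNA) network
    analysis of paired tumour/normal RNA-seq and miRNA-seq count data:
    TMM normalisation and logCPM filtering, empirical-Bayes moderated-t
    differential expression, triple-evidence ceRNA pair inference
    (shared-miRNA hypergeometric test, lncRNA-mRNA expression
    correlation, regulation similarity over shared miRNAs), network
    assembly with Cytoscape-compatible export, and median-split
    univariate Kaplan-Meier/log-rank survival screening. Ships a seeded
    negative-binomial multi-omic simulator with planted differential
    expression, ceRNA triples and expression-linked survival so the
    whole pipeline can be exercised end to end against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    edgeR,
    limma,
    survival,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
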