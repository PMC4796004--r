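Package: AtomicRegulons
Title: Atomic Regulon Inference and Regulatory Network Reconciliation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers Atomic Regulons (ARs) -- sets of genes with identical
    binary ON/OFF expression profiles across a compendium of expression
    samples -- by seeding with crude operon predictions and subsystem-based
    draft regulons, then decomposing and expanding the drafts against
    binarized expression data. Provides a data model for stimulus-annotated
    transcriptional regulatory networks (regulators, mechanism categories,
    effectors, target genes), derives stimulons, and reconciles inferred ARs
    against the network through a four-way consistency classification
    (consistent, consistent with missing stimuli, inconsistent, empty) with
    curation operators, stimulus propagation proposals, hypergeometric
    enrichment of sample metadata for stimulus inference, and an
    essential-gene sanity check. Ships a ground-truth synthetic compendium
    generator so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
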