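Package: solgrn
Title: Consensus Differential Expression Meta-Analysis and Integrative
    Gene Regulatory Networks for Plant Stress Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrative meta-analysis of drought and heat stress
    transcriptomes in Solanaceae crops. Implements consensus differential
    expression across independent experiments (negative-binomial threshold
    Wald tests, empirical-Bayes false-sign-rate shrinkage, occurrence-group
    ranking and top-set selection), promoter motif enrichment against a
    position-weight-matrix library, adaptive-threshold co-expression and
    topological-overlap module detection, tri-evidence gene regulatory
    network assembly (co-expression, motif, protein-protein interaction)
    with evidence-priority clustering and hub calling, cross-species
    ortholog direction concordance, and NG86 Ka/Ks selection-regime
    contrasts. Ships a synthetic-data generator with known ground truth so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    limma,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
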