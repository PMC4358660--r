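Package: moanet
Title: Drug Mechanism-of-Action Inference by Expression-Weighted Network Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers drug mechanism of action by diffusing chemical-proteomics
    target profiles over a cell-state-specific protein-protein interaction
    network. The network is restricted to expressed genes (FPKM filter) and
    edges are weighted by transcriptional co-regulation under treatment; a
    random walk with restart propagates spectral-count-derived seed
    probabilities, node and gene-set significance are assessed against
    permutation nulls with Benjamini-Hochberg control, and leave-one-target-out
    reruns rank individual targets by their impact on enriched gene sets.
    Companion tools cover high-throughput screen triage (per-plate
    normalization, control-based z-score hit calling, Jaccard/Tanimoto
    clustering of hit fingerprints) and Bliss-independence synergy analysis of
    dose-response matrices. A synthetic-data module generates every input with
    ground-truth labels so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    Matrix,
    fgsea,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
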