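Package: peakforge
Title: GAS-Motif-Anchored Peak Confidence, Enhancer-Cluster Calling, and
    Binding-Expression Integration
Version: 0.1.0
Authors@R: person("peakforge", "developers", role = c("aut", "cre"),
    email = "peakforge@example.org")
Description: Downstream regulatory-genomics toolkit for transcription-factor
    ChIP-seq peak post-processing. Identifies high-confidence TF binding
    peaks as those coinciding with H3K27ac marks within a configurable
    window and containing at least one GAS element (5'-TTCNNNGAA-3') in the
    peak region; stitches peaks into candidate regulatory regions and calls
    enhancer clusters (super-enhancers) by the tangent-slope method on the
    normalized rank-score curve; assigns peaks to genomic feature categories
    (promoter, 3'UTR, exon, intron, distal, intergenic) with target-gene
    linking; and integrates binding with per-gene differential-expression
    statistics (count prefilter, Benjamini-Hochberg adjustment, fold-change
    thresholds, Venn decomposition) to nominate bona fide target genes.
    Ships a deterministic synthetic-fixture generator with a planted ground
    truth manifest, and a command-line pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
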