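Package: kairoscan
Title: Bivalent Chromatin Detection over Metabolic Pathway Annotation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Integrates binned, rank-normalized epigenomic signal tracks with a
    metabolic-network gene annotation to detect histone-mark enrichment and
    bivalent (co-marked) chromatin on metabolic pathways. Aggregates per-mark
    signal over gene windows (transcribed region plus 1 kb upstream and 500 bp
    downstream), computes per-set signal densities against a metabolic-gene
    background, calls enrichment or depletion by density fold change with
    Fisher's exact test and Benjamini-Hochberg FDR, quantifies mark
    co-occurrence and correlation attribution, and provides the ChIP-qPCR,
    sequential-ChIP and expression-kinetics calculators (percent input,
    relative abundance, percent-of-first-ChIP, delta-delta-Cq fold change,
    three-way factorial ANOVA) used to validate bivalent loci. A seeded
    synthetic-data module generates every input format with planted ground
    truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
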