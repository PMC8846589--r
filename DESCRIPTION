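Package: regulonscan
Title: Terminal-Selector Regulon Analysis from ChIP Peaks, Expression, and
    Metacell Data
Version: 0.1.0
Authors@R:
    person("Regulonscan", "Developers", email = "regulonscan@example.org",
           role = c("aut", "cre"))
Description: Derives the direct-target regulon of a terminal-selector
    transcription factor from replicated ChIP-seq peaks, gene models, a
    differential-expression table, and a single-cell metacell footprint
    matrix. Builds replicate-consensus peaks by overlap grouping and Fisher
    p-value combination, scans genomic sequence for degenerate (IUPAC)
    consensus binding motifs with a positional central-enrichment test,
    assigns peaks to genes by a strand-aware promoter-plus-gene-body
    territory rule, splits direct targets into directly-activated and
    directly-repressed sets against mutant-vs-sibling differential
    expression, summarizes per-cell-type regulon composition (repression
    proportion, exclusive markers), and performs hypergeometric
    overrepresentation testing with Benjamini-Hochberg correction. A seeded
    synthetic-study generator with planted ground truth makes every stage
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
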