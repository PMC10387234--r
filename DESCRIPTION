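Package: serumiR
Title: Serum Small RNA-Seq miRNA Profiling with an Exact Count-Based
    Differential Test
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for serum small RNA sequencing studies:
    read quality control and adapter trimming, exact-match mature miRNA
    quantification against a small-RNA reference, transcripts-per-million
    (TPM) normalization with a zero floor for group-level values, an exact
    count-based differential-expression test for pooled digital tag counts
    (Audic-Claverie style), fold-change/p-value selection of differential
    miRNAs, consensus intersection of multi-source miRNA target
    predictions, miRNA-mRNA regulatory network export, hypergeometric
    term-enrichment analysis, and delta-delta-Ct relative quantification
    for qPCR validation. Ships seeded simulators for every input (reference
    sequences, count matrices, adapter-ligated FASTQ reads, target lists,
    annotation maps, Ct tables) so the whole pipeline is testable end to
    end without external downloads, plus a replay mode that re-derives
    fold-change statistics from published group-TPM tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
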