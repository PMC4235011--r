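Package: ripchip
Title: RIP-Chip Analysis of Argonaute-Bound miRNA Targets on Two-Channel
    Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying microRNA target mRNAs from Argonaute
    immunopurification (RIP-chip) experiments profiled on two-channel
    oligonucleotide microarrays. Provides element-level quality filtering
    and global median normalization of log2 ratios, a SAM-style moderated
    enrichment statistic with a permutation null and local false discovery
    rate estimation for calling RISC-recruited transcripts, seed-match
    classification of 3' UTRs into the canonical site types (8mer, 7mer-m8,
    7mer-1A and two 6mer variants), stratified cumulative-distribution
    analysis of recruitment efficiency by site type, average-linkage
    hierarchical clustering of called targets, a degenerate TCF/beta-catenin
    motif scanner, and a synthetic-data generator with planted ground truth
    for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
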