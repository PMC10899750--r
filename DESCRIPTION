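Package: dicerscan
Title: High-Throughput Dicing Assay Analysis for DICER Cleavage-Site Mapping
Version: 0.1.0
Authors@R:
    person("dicerscan", "developers", email = "dicerscan@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput dicing assays performed on
    barcoded two-loop short-hairpin RNA (shRNA) libraries. Covers the full
    path from sequencing reads of original substrates and cleaved products to
    per-variant DICER cleavage-site calls, cleavage efficiency and accuracy
    scores, six-symbol secondary-structure annotation, min-max rescaled
    mWCU and YCR motif scores, and applications of those scores to
    pre-miRNA hairpins (SNP impact, upstream motif enrichment, isomiR DCx
    classification). Ships a simulator that generates randomized hairpin
    libraries and cleavage reads under a two-motif multinomial site model
    for the wild-type enzyme and dsRBD mutants, so every stage of the
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
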