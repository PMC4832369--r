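Package: bisamp
Title: Multiplex Bisulfite Amplicon Sequencing Analysis of Per-Read CpG
    Methylation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for targeted multiplex bisulfite amplicon
    sequencing assays such as FOXP3 TSDR-based regulatory T cell (Treg)
    enumeration. Demultiplexes dual-placement indexed FASTQ reads, assigns
    reads to amplicons by primer, calls a per-read methylation pattern
    (epiallele) at each targeted CpG site, quantifies pattern frequencies,
    k-of-n demethylation distributions and Treg-like read fractions with
    replicate summaries and titration regression, and reports bisulfite
    conversion efficiency from non-CpG cytosines. Includes a seeded read
    simulator emulating cell-type mixtures, incomplete conversion,
    sequencing error and female X-inactivation dosage, so every stage is
    testable end-to-end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    readr,
    tibble,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
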