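Package: paralogmeth
Title: Paralog-Specific CpG Methylation from Bisulfite Pyrosequencing and
    High-Resolution Melting
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies locus-specific CpG methylation when two highly similar
    gene paralogs (such as CDKN2A exon 2 and CDKN2B exon 2) are unavoidably
    co-amplified by a single bisulfite PCR. Pyrosequencing peak patterns at
    paralog-discriminating positions estimate the proportion of each paralog in
    the product pool; per-CpG methylation is corrected for cross-paralog
    signal, substituted at the limits of quantification, and tiered by
    reliability. Also provides high-resolution melting (HRM) quantification via
    temperature-wise cubic calibration against methylation standards,
    in-silico bisulfite conversion, primer matching and amplicon prediction
    (genomic and spliced transcripts), and fully seeded simulators for
    pyrograms and melt curves so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
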