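Package: ervscreen
Title: Case-Control Screening of Insertionally Polymorphic Endogenous
    Retroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening human endogenous retrovirus (HERV-K/HML-2)
    insertion polymorphisms in case-control cohorts. Implements probe
    selection from an identity-ranked proviral alignment, restriction-enzyme
    selection and provirus-host junction-fragment prediction (a "virtual
    unblot"), collation of per-individual band patterns into cross-cohort
    clusters with novel-insertion flagging, three-primer in silico PCR allele
    genotyping (provirus / solo LTR / pre-integration site), and carrier
    frequency association statistics (uncorrected Pearson chi-square,
    two-proportion sample-size and Monte-Carlo power). A synthetic cohort
    generator produces reference panels and diploid Hardy-Weinberg cohorts
    with known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
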