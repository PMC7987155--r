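Package: regulonscan
Title: Methylation-Aware Promoter Motif Scanning and Regulon Conservation
    Analysis for Alphaproteobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bacterial cell-cycle regulons built around
    the CcrM adenine methyltransferase and the GcrA transcription factor.
    Provides position-specific scoring matrix (PSSM) and mixture-motif
    construction with exact background score distributions and information
    content based threshold calibration; genome-wide IUPAC motif enumeration
    and operon-aware promoter scanning; strand-resolved 6mA methylation
    calling from SMRT interpulse-duration (IPD) ratios; differential
    expression and ChIP-peak based regulon definition with cross-species
    comparison cascades; an ortholog-group conservation statistic (mean best
    site score weighted by site pervasiveness and site count) with posterior
    probabilities of regulation; and seeded synthetic-data generators that
    emulate every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    Biostrings,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
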