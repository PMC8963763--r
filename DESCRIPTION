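Package: methcascade
Title: Promoter Methylation Biomarker Discovery from Two-Channel CpG Island Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Pipeline for discovering and validating promoter-methylation
    biomarkers of chemoradiotherapy response from two-channel CpG-island
    methylation arrays. Computes the bi-weight (BW) intensity ratio per
    probe, calls differentially methylated regions between responder
    groups, summarises probes to regions, and runs a marker-selection
    cascade based on gene-level median differences and promoter CpG-island
    density. Includes in-silico bisulfite conversion and methylation
    specific PCR (MSP) status logic, chi-square association tests and
    Kaplan-Meier / log-rank survival comparisons for validation cohorts,
    and seeded simulators for arrays, promoter sequences and clinical
    cohorts with planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
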