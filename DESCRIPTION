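Package: tedose
Title: Relative Allele Dosage of Retrotransposon Insertions from qPCR-RBIP Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the qPCR-RBIP marker system: estimate per-reaction
    amplification efficiency and Ct from raw real-time PCR fluorescence
    curves using a window-of-linearity fit, apply replicate quality-control
    rules, and convert the efficiency-corrected presence:absence Ct ratio
    into a relative allele dosage score out of 10 for retrotransposon
    insertion sites in polyploid genomes. Per-sample transposable-element
    profiles are compared with the Nei-Li (Dice) distance and clustered by
    UPGMA with bootstrap support, and LTR retrotransposon insertions are
    dated from 5'/3' LTR divergence (Kimura two-parameter distance) under a
    molecular clock. A simulation module generates synthetic qPCR plates
    with known allele dosage and synthetic LTR pairs with known age for
    closed-loop validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vegan,
    Biostrings,
    yaml,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
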