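Package: minisplice
Title: Minigene Splice-Assay Quantification and ACMG Splice-Evidence
    Reclassification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of minigene splice assays used
    in clinical variant interpretation: a coding-coordinate (HGVS c.)
    transcript model with minigene construct geometry, SpliceAI-threshold
    variant prioritization from LOVD/ClinVar-style tables, densitometric
    quantification of RT-PCR products from gel-lane intensity profiles,
    HGVS r./p. consequence annotation of aberrant splice products, and a
    gene-specific ACMG/ClinGen rule engine (PVS1 strength modifiers and
    BP7-strong RNA evidence) driven by residual wild-type transcript
    fractions. Includes seedable generators for synthetic transcript models,
    variant tables and gel lanes with ground truth, so every stage can be
    exercised and validated offline.
License: MIT + file LICENSE
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
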