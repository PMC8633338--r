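Package: mhtrace
Title: Screening and Pedigree Tracing of Actionable Malignant Hyperthermia Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population screening of medically actionable variants in the
    malignant hyperthermia susceptibility genes RYR1 and CACNA1S, and for pedigree-aware
    inference of a variant's origin. Implements rare-variant filtering of a sequenced
    cohort with ClinVar-style classification aggregation and carrier-frequency
    estimation; an exact binomial allelic-balance test that flags somatic/germline
    mosaicism from read depths; shared-haplotype segment tracing through
    parent-of-origin phased pedigrees to the originating individual; the malignant
    hyperthermia clinical grading score; and a gene-dropping simulator that generates
    pedigrees, phased haplotypes, read depths and cohort tables with a ground-truth
    ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
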