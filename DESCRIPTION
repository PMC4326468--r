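Package: embryoscreen
Title: Shallow Whole-Genome Sequencing Copy-Number Screening for Embryo Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Copy-number analysis of low-coverage whole-genome sequencing from
    whole-genome-amplified embryo biopsies, as used in preimplantation genetic
    diagnosis and screening. Bins aligned read positions, removes GC/WGA
    coverage bias, locates copy-number breakpoints by recursive binary
    segmentation with a permutation stopping rule, filters calls with
    per-sample dynamic thresholds, classifies embryo karyotypes (euploid,
    numerical, imbalanced, numerical+imbalanced) and renders band-level
    "seq" call nomenclature. Also estimates relative mitochondrial DNA copy
    number from depth ratios with a Mann-Whitney group comparison, computes
    clinical outcome contingency statistics, and ships a seeded synthetic-data
    generator (GC-biased, negative-binomially overdispersed read counts over
    configurable genomes and karyotypes) so the whole pipeline is testable
    without access to patient sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
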