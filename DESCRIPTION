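Package: sexmarkr
Title: Discovery of Sex-Linked Variants and Design of PCR Sex-Identification Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering sex-determination regions from
    multi-sample genotype data in species without sexual dimorphism.
    Screens a male/female diploid genotype matrix for variants with strict
    sex-specific segregation using an exact test on the 2-by-3 sex-by-genotype
    table at a genome-wide significance threshold, applies an exact
    Hardy-Weinberg filter, infers the heterogametic system (XY or ZW),
    partitions candidate regions into linkage-disequilibrium blocks with the
    confidence-interval (Gabriel) method driven by a two-locus EM haplotype
    estimator, selects diagnostic markers, and evaluates presence-type,
    allele-specific and indel-size PCR sex-calling assays in silico. Includes
    a synthetic-cohort simulator with planted sex-determination regions and
    truth files for parameter-recovery validation.
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
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    BiocGenerics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
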