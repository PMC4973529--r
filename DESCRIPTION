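Package: crossboa
Title: Breed-of-Origin Assignment of Alleles in Three-Way Cross Livestock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns the breed-of-origin of each allele carried by
    three-way crossbred animals (terminal sire line S on an F1 dam of
    Landrace x Large White) from phased SNP genotypes. The genome is
    segmented into haplotype core windows under eighteen configurations
    (nine core:tail lengths, each with and without a half-core offset), a
    haplotype library with per-breed copy counts is built from the
    purebred populations, window haplotypes of crossbreds are matched to
    the library and assigned a breed under a relaxation factor, and a
    per-allele consensus constrained by zygosity and breed composition
    yields breed-of-origin tracks. Includes a three-way-cross simulator
    with exact per-allele origin truth (Balding-Nichols breed divergence,
    random-mating purebred histories, recombination, genotype and
    phasing-switch error injection), trio phasing, imputation-accuracy
    metrics (concordance and MAF-corrected correlation), and G-matrix
    principal-component screening for mislabelled animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
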