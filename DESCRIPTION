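Package: haplodose
Title: Haplotype Inference in Polyploids from Bi-Allelic SNP Dosage Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs multi-allelic haploblock genotypes (haplotype
    combinations) of autopolyploid individuals from bi-allelic SNP dosage
    data. Sets of tightly linked SNPs are treated as one multi-allelic
    locus; all haplotype combinations compatible with the observed marker
    dosages are enumerated exhaustively, a parsimonious inventory of
    haplotypes is built for the population, and full-sib families are
    resolved by scoring candidate parental haplotype combinations against
    the observed offspring segregation with a chi-squared goodness-of-fit
    test that accounts for double reduction and dosage-scoring errors.
    Includes a seeded simulator of tetraploid full-sib populations for
    validation, truth-based scoring, replicate merging, and
    parent-offspring compatibility checks against a pedigree.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
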