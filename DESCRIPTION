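Package: hapblup
Title: Haplotype-Based Genomic Prediction from LD-Defined Haploblocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic prediction with haplotype alleles built from
    linkage-disequilibrium (LD) defined haploblocks. Provides a forward-in-time
    simulator of two populations diverged by drift with repeated-record
    phenotypes; phased-genotype input (VCF, PLINK) with variant quality
    control; pairwise-r2 haploblock construction at a ladder of LD thresholds
    with numerical dosage recoding of haplotype alleles; SNP and haplotype
    genomic relationship matrices; a pedigree repeatability animal model for
    corrected phenotypes; average-information REML fitting of GBLUP, GHBLUP
    and two-component GH+GBLUP predictors; and forward-validation accuracy
    and bias evaluation over scenario grids.
License: MIT + file LICENSE
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
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
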