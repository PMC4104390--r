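Package: snph2
Title: SNP Heritability of Rare Binary Traits from Ascertained
    Case-Control Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the proportion of variance in liability to a rare
    binary trait that is captured by common SNPs, from ascertained
    case-control genotype data.  Implements the GREML approach for binary
    traits: construction of the genetic relationship matrix (GRM) from
    PLINK-format genotypes, restricted maximum likelihood (AI-REML)
    fitting of a mixed linear model on the observed 0/1 scale, and
    transformation of estimates to the liability scale with ascertainment
    correction at a stated population prevalence.  Supports partitioning
    heritability by chromosome, principal-component adjustment for
    population structure, a shrinkage correction of the GRM for
    prediction error due to imperfect linkage disequilibrium, and a
    synthetic-cohort generator (liability-threshold trait, low-prevalence
    ascertained sampling, optional two-subpopulation structure) for
    robustness experiments: subsampling stability at moderate sample
    sizes and a controls-coded-as-cases negative control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
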