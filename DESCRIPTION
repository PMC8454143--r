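Package: rohtrait
Title: Runs of Homozygosity Detection and Association with Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) from SNP-array genotypes with a
    sliding-window screen and six segment criteria (minimum length, SNP count,
    density, inter-SNP gap, heterozygote and missing-call allowances),
    summarises ROH by individual, chromosome and size class, computes the
    genomic inbreeding coefficient FROH, builds consensus ROH and
    high-frequency ROH islands across a population, and tests ROH regions for
    association with quantitative production traits via extreme-group Fisher
    enrichment followed by a genomic-relationship-matrix REML mixed model.
    Includes PLINK PED/MAP and BED/BIM/FAM readers and writers, exact
    Hardy-Weinberg and Fisher tests, two-locus EM linkage-disequilibrium
    estimation, and a seeded simulator that plants autozygous segments and
    trait effects with full truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
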