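Package: trioscreen
Title: Trio De Novo Calling and Digenic Screening for Rare-Disease Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-scale workflow for trio exome studies of rare disease:
    multi-sample VCF + pedigree ingestion with hard genotype and site filters
    (genotype quality, depth, allele balance, missingness, Hardy-Weinberg
    exact test), functional classification of annotated variants (LGD, D-mis,
    rarity), de novo variant identification in proband-parent trios with a
    Poisson mutation-rate burden test, an exome-wide screen for case-specific
    digenic combinations of rare deleterious variants in haploinsufficient
    (pLI > 0.9) genes, cohort reporting (diagnostic yield, suture
    distribution, multilocus pathogenic variation), and a fully deterministic
    synthetic trio-cohort simulator with planted truth for end-to-end
    validation.
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
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
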