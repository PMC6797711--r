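Package: trioscape
Title: Burden-Aware Enrichment and Belief-Network Landscapes for Trio Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the genetic architecture of congenital
    heart disease (CHD) trio cohorts. Provides a burden-aware permutation
    test for gene-list enrichment of damaged de novo and recessive
    genotypes (empirical p-values, Z standardization, fold enrichment),
    decile burden-matched control gene lists, damaged-genotype filtering
    with population-attributable-risk and allele-frequency criteria,
    expected population genotype frequencies for recessive and
    compound-heterozygous genotypes, trio-level quality control,
    laterality-phenotype association with Benjamini-Hochberg control, and
    a discrete belief-network layer with exact AIC-optimal structure
    learning, exact inference, risk-ratio queries, bootstrap edge support
    and nested likelihood-ratio tests. A fully parameterized synthetic
    trio-cohort generator with recorded ground truth lets every analysis
    run and be validated without access to controlled patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
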