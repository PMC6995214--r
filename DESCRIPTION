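Package: lohstrat
Title: Genomic Subtyping of Liver Cancers by SNV Load, LOH, Mutational
    Signatures and Survival-Associated Recurrent CNVs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies tumor cohorts into long- and short-survival
    subgroups from four whole-genome mutational markers: somatic SNV load,
    the percentage of loss-of-heterozygosity (LOH) mutations, the exposure
    to the major of two mutational signatures resolved by bootstrapped
    non-negative matrix factorization over the 96 trinucleotide contexts,
    and the burden of survival-associated recurrent copy-number variants
    (srCNVs) detected in 350-kb windows by a Poisson recurrence cutoff and
    log-rank screening. Includes classification of paired blood-tumor
    genotype calls into gain- and loss-of-heterozygosity mutations,
    region-subset extraction with load renormalization, optimal-cutpoint
    log-rank stratification, bootstrapped hierarchical clustering of srCNV
    carriage, Kaplan-Meier / Cox summaries, and a synthetic-cohort
    generator that emulates the statistical structure of a liver-cancer
    whole-genome study so that every stage is testable without
    controlled-access data.
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
    IRanges,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
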