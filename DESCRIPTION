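Package: pinegs
Title: Genomic Selection Evaluation for Clonally Replicated Tree Breeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate genomic selection for low-heritability categorical
    traits in clonally replicated forest-tree breeding trials. Implements
    SNP-based pedigree correction by trio-exclusion parentage assignment,
    pedigree (ABLUP) and genomic (GBLUP) best linear unbiased prediction with
    EM-REML variance components under heterogeneous per-site variance
    structures, heritability, accuracy and marker-captured additive-variance
    summaries, replicated k-fold cross-validated predictive ability, and the
    relative efficiency of genomic over pedigree-based forward selection.
    Includes a simulator of multi-site clonal trial datasets with known genetic
    truth and configurable pedigree-error, genotyping-error and missingness
    rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Matrix,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
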