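Package: snpcombo
Title: Exhaustive SNP-Combination Risk Scanning for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genetic epidemiology of case-control cohorts genotyped
    at a small panel of biallelic SNPs and deletion polymorphisms. Enumerates
    all dominant/recessive risk indicators and their k-way conjunctions,
    scores each conjunction with a 2x2 odds ratio, Woolf confidence interval
    and Bonferroni-adjusted Wald test, stratified by smoking status; provides
    permutation calibration of the chi-squared(1) approximation, bootstrap
    rank-stability summaries, logistic-regression adjusted odds ratios with a
    stratum-heterogeneity (interaction) test, and population attributable
    risk calculators (Levin, case-based, multi-level, combined) together with
    the PAR/relative-risk/frequency algebra. A synthetic cohort generator
    with Hardy-Weinberg genotypes, configurable smoking strata and planted
    conjunction effects makes every pipeline stage testable without
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
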