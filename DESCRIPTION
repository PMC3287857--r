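Package: nestpath
Title: Two-Stage Nested Random-Effects Pathway Association Tests for Family Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pathway (SNP-set) association testing for sibship-structured and
    unrelated samples using a two-stage approach. Stage one fits a binomial
    logistic mixed model to the genotypes of a pathway with nested random
    effects (sibship, subject, gene-within-subject) by a Laplace-approximate
    marginal likelihood, and summarizes each subject's multi-SNP burden per
    gene by the empirical Bayes (conditional mode) estimate of the
    gene-within-subject effect. Stage two enters these summaries as covariates
    in family-aware phenotype models: a linear mixed model with a sibship
    random effect for quantitative traits, and a logistic GEE with
    exchangeable working correlation for binary traits. Pathway, gene-level,
    and gene-by-environment effects are tested with Wald chi-square
    statistics. Includes readers for PLINK .raw/.fam, TSV and minimal VCF
    input, a sibship-structured genotype/phenotype simulator, and an
    operating-characteristics harness for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    vcfR,
    optparse
Config/testthat/edition: 3
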