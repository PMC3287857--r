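---
title: "Two-stage nested random-effects pathway tests: models and methods"
author: "nestpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage nested random-effects pathway tests: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-SNP association tests are underpowered when many variants in a
biological pathway each contribute a small effect, and especially so for
rare variants. nestpath tests for the *joint* effect of all SNPs in a set of
genes (a pathway) on a phenotype, in samples that may contain sibships.
The key idea is to model the correlation of SNPs *within* genes and
*between* genes explicitly with nested random effects, compress each
subject's multi-SNP genotype information into one empirical Bayes (EB)
burden score per gene, and then carry those scores into an ordinary
phenotype regression where pathway, gene and gene-by-environment hypotheses
become Wald tests on a handful of coefficients. No permutations are needed:
the test statistics follow chi-square distributions under the null.

# Stage 1: the genotype (gene) model

Index sibships by $i$, subjects by $j$, genes by $g = 1,\dots,G$, and SNPs
within gene $g$ by $s = 1,\dots,S_g$. Genotypes $w_{ijgs} \in \{0,1,2\}$
count minor alleles (the readers enforce this orientation). Under
Hardy–Weinberg equilibrium each genotype is $\mathrm{Binomial}(2,
\pi_{ijgs})$ given the random effects, with

$$\mathrm{logit}(\pi_{ijgs}) = \beta_{0s} + z_{ij}'\alpha + b_i + b_{ij} + b_{ijg},$$

where $b_i \sim N(0, \sigma^2_{sib})$ is a sibship effect (shared genetic
background of siblings), $b_{ij} \sim N(0, \sigma^2_{subj})$ a subject
effect (a subject's overall pathway burden, inducing between-gene
correlation), and $b_{ijg} \sim N(0, \sigma^2_{gene})$ a gene-within-subject
effect (inducing within-gene correlation between SNPs). For unrelated
(all-singleton) samples the sibship term is dropped.

**Per-SNP intercepts.** The fixed part uses one intercept per SNP
($\beta_{0s}$) by default. Minor allele frequencies in a pathway typically
span two orders of magnitude, so a shared or per-gene intercept would force
the random effects to absorb frequency differences and corrupt the burden
interpretation. `per_gene` and `shared` modes exist for constrained
designs.

**Fitting.** The marginal likelihood integrates over all random effects;
nestpath maximizes its Laplace approximation. Conditional modes of
$(\beta, b)$ are found by penalized iteratively reweighted least squares
(PIRLS) on the sparse joint system, in the "spherical" parameterization
$b = \sigma u$, $u \sim N(0, I)$, which keeps the objective well defined
when a standard deviation reaches 0. The profiled Laplace objective is then
optimized over the random-effect standard deviations: Brent search for a
single component, Nelder–Mead (on magnitudes, so the boundary is reachable
by reflection) for several, with estimates below $10^{-5}$ snapped to the
boundary 0. We optimize standard deviations rather than log-variances
precisely because boundary estimates ($\hat\sigma = 0$) are legitimate
outcomes that a log scale cannot represent. Everything is deterministic:
random effects start at zero, fixed effects at empirical-logit values.

Convergence uses a relative log-likelihood tolerance of $10^{-8}$
(`gene_model_spec(reltol=)`) with an iteration cap of 500; the inner PIRLS
iterates Newton steps with step-halving until the penalized log-likelihood
changes by less than $10^{-10}$ (relative).

**Missing genotypes** are handled by cell-wise deletion inside the
likelihood: the subject stays in the model and its remaining cells still
inform its random effects. No imputation is performed.

**Validation against exact integration.** Because the random effects are
nested, the exact marginal likelihood factorizes into a recursion of 1-D
integrals. `loglik_oracle()` evaluates it by adaptive Gauss–Hermite
quadrature (nodes centred at the mode of each integrand) and is the
package's independent accuracy check: on a 2-sibship × 2-subject × 2-gene
fixture the Laplace value agrees within 1% (the test suite asserts this),
and with all variances fixed at 0 both collapse exactly to the independent
binomial GLM.

# The empirical Bayes burden score

The EB estimate for subject $j$ and gene $g$ is the conditional (posterior)
mode $\hat b_{ijg}$ of the gene-within-subject effect at the fitted
parameters — identical to the conditional mean under the Laplace Gaussian
approximation. It is a one-number summary of the subject's multi-SNP burden
in that gene: holding everything else fixed, each additional minor allele in
gene $g$ strictly increases $\hat b_{ijg}$. With $\hat\sigma^2_{gene} = 0$
all scores are exactly zero, in which case no pathway test is possible (the
operating-characteristics harness records such replicates as failures
rather than silently dropping the term).

EB scores enter stage 2 unstandardized. Scaling a column would rescale its
$\gamma_g$ without changing any Wald statistic, so standardization is left
to the user.

# Stage 2: phenotype models and tests

For a quantitative trait $y_{ij}$ we fit the linear mixed model

$$y_{ij} = x_{ij}'\beta + \sum_g \gamma_g \,\hat b_{ijg} + u_i + e_{ij},$$

with a normal sibship effect $u_i$ and residual $e_{ij}$, by maximum
likelihood via lme4. ML (not REML) is the default so that the Wald
covariance and any likelihood comparisons are internally consistent; REML
is available behind `phenotype_model_spec(reml=)`. With all-singleton
sibships $\sigma^2_u$ and $\sigma^2_e$ are confounded; the implementation
profiles $\sigma^2_u$ to the boundary 0, where the coefficients coincide
with ordinary least squares.

For a binary trait we fit the marginal logistic model
$\mathrm{logit}\,P(y_{ij}=1) = x_{ij}'\beta + \sum_g \gamma_g \hat b_{ijg}$
by GEE with an exchangeable working correlation within sibships
(Liang–Zeger moment estimator for $\rho$, estimated scale, robust sandwich
covariance). A marginal model with a sandwich is less efficient than a
likelihood-based mixed model but requires no integral over a binary-trait
random effect and is robust to misspecifying the within-sibship
association. With clusters of size one it reduces exactly to ordinary
logistic regression with the HC0 sandwich.

Gene-by-environment terms are products of an EB column with a covariate
(e.g. a gene's burden × smoking status) and are added as ordinary columns.

**Tests.** The pathway null $H_0: \gamma_1 = \dots = \gamma_G = 0$ is
tested by $W = \hat\gamma' \hat V_\gamma^{-1} \hat\gamma$ against
$\chi^2_G$, using the model-based covariance for the LMM and the sandwich
for the GEE. Interaction coefficients are *not* part of the pathway null
(they are reported separately); a flag gives the joint $(G+k)$-df test.
Gene-level tests are 1-df Walds on single $\gamma_g$ from the *joint* fit,
i.e. conditional on the other genes' scores. A singular $\hat V_\gamma$ is
an error by default; an explicit `pseudo_inverse` mode tests on the
effective rank and flags the report. Gene-level p-values are reported raw
(no multiplicity adjustment), matching how per-gene results are
conventionally displayed next to the single pathway test; users needing
familywise control can apply `p.adjust` to the reported column.

**Collapsed rare-variant test.** `collapsed_rare_test()` pools all variants
with MAF below a threshold (default 0.05) into one pseudo-gene, yielding a
single EB column and a 1-df burden test — more powerful when weak
rare-variant signal is spread over many genes, at the cost of discarding
the within-gene structure (so gene-specific interactions cannot be
modelled in this mode).

# The simulator

`simulation_scenario()` + `simulate_dataset()` generate data from exactly
the models above: genotypes from the nested binomial model at stated MAFs
(rare and common; MAFs enter on the logit scale as the SNP intercepts),
phenotypes from the stage-2 LMM or from a direct logistic model for binary
traits. The drawn $b_{ijg}$ are the true gene scores; the phenotype effect
$\gamma$ applies to these draws, which makes stage-2 recovery well defined
and lets power studies vary a single knob.

Defaults describe a realistic sibling-based study: sibships of sizes 1–6,
Age $\sim N(50, 10^2)$ years, Smoking $\sim \mathrm{Bernoulli}(0.25)$,
baseline prevalence 0.3 for binary traits, genotype-model variances
$(\sigma^2_{sib}, \sigma^2_{subj}, \sigma^2_{gene}) = (0.2, 0.3, 0.5)$ and
phenotype variances $(\sigma^2_u, \sigma^2_e) = (0.5, 1)$. A family design's
enrichment of rare variants is emulated by specifying larger MAFs in the
family scenario rather than by modelling an ascertainment mechanism;
likewise binary traits are generated directly from the marginal logistic
model, not through a latent liability. Real sequence data differ in ways
the generator does not emulate — linkage disequilibrium beyond what the
random effects induce, allele-frequency spectra from demography,
ascertainment of families through affected probands, and correlated
secondary traits — so passing operating-characteristics tests demonstrate
internal consistency of the method under its own model, not calibration on
any particular study design.

`run_operating_characteristics()` derives one sub-seed per replicate from
the global seed by a fixed counter scheme (replicates are independent and
order-insensitive), excludes non-converged replicates from the denominator
(reporting their count, aborting above 20%), and returns rejection rates
with Monte-Carlo standard errors.

# Validation sizes and empirical behaviour

The test suite exercises, among others: nominal size of the full two-stage
pipeline (200 null replicates of 600 singleton subjects, $G = 3$ genes × 4
SNPs, MAFs 0.05–0.4, accepted inside the 95% binomial interval around 5%);
variance-component recovery within ±50% in at least 80% of 20 replicates at
2,000 subjects in sibships of four ($G = 5$); power monotonicity across
$\gamma \in \{0, 0.3, 0.6\}$ with paired seeds (100 replicates each); and a
family-versus-unrelated power contrast with equal total sample size and
rare variants enriched in the family scenario. These sizes were chosen to
give stable Monte-Carlo estimates while keeping the full suite comfortably
runnable on a single CPU.

# Numerical choices and edge cases

* PIRLS weights are floored at $10^{-10}$; fitted probabilities never reach
  0 or 1 exactly on the logit scale.
* Variance components estimated below $10^{-5}$ (SD scale) are reported as
  exactly 0, and a zero component contributes nothing to the linear
  predictor (its spherical coordinates shrink to the prior mode).
* Minor-allele orientation flips codes when the coded-allele frequency
  exceeds 0.5; an exact tie keeps the original orientation.
* Monomorphic SNPs are removed before fitting; genes left empty disappear
  from the gene map; an entirely monomorphic pathway is an error.
* The GEE working correlation is clamped to the valid exchangeable range
  for the largest cluster; separation is detected as a diverging linear
  predictor and raised as a classed error.
* The quadrature oracle caps the per-sibship random-effect dimension at 8;
  it is a verification tool for tiny fixtures, not a production fitter.

# Known limitations

* The Laplace approximation for binomial size-2 data carries a downward
  bias in $\hat\sigma^2_{gene}$ of order 10–20% at realistic sizes; the
  recovery checks in the test suite allow for it. Adaptive-quadrature
  production fitting is deliberately out of scope.
* Relatedness beyond sibships (e.g. cousin-level correlation) is not
  modelled in either stage.
* The binary-trait branch has no likelihood, hence no likelihood-ratio
  pathway test; only Wald tests are offered.
* No LD pruning, kinship estimation, imputation or phasing: inputs are
  assumed analysis-ready.
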