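# --- closed-form and oracle checks ------------------------------------------

test_that("with variance components fixed at 0 the fit is the binomial GLM", {
  # 100 singleton subjects, one SNP, 20 minor alleles in 200 chromosomes
  m <- matrix(c(rep(1L, 20), rep(0L, 80)), ncol = 1,
              dimnames = list(sprintf("s%03d", 1:100), "snp1"))
  b <- make_bundle(m, sprintf("f%03d", 1:100), c(snp1 = "g1"))
  fit <- fit_gene_model(b, gene_model_spec(
    fixed_variance = c(sib = 0, subj = 0, gene = 0)))
  expect_equal(unname(fit$fixed_effects[["snp1"]]), qlogis(0.1),
               tolerance = 1e-6)
  expect_equal(unname(fit$fixed_effects[["snp1"]]), -2.1972,
               tolerance = 1e-4)

  # multi-SNP, multi-gene case against glm() IRLS
  bb <- tiny_bundle()
  fit0 <- fit_gene_model(bb, gene_model_spec(
    fixed_variance = c(sib = 0, subj = 0, gene = 0)))
  mm <- bb$genotypes$matrix
  long <- data.frame(w = as.vector(mm),
                     snp = factor(rep(colnames(mm), each = nrow(mm)),
                                  levels = colnames(mm)))
  g <- glm(cbind(w, 2 - w) ~ 0 + snp, family = binomial(), data = long)
  expect_equal(unname(fit0$fixed_effects), unname(coef(g)), tolerance = 1e-6)
  expect_equal(fit0$log_likelihood, as.numeric(logLik(g)), tolerance = 1e-8)
  # the quadrature oracle reduces to the same GLM log-likelihood exactly
  expect_equal(loglik_oracle(bb, fit0), as.numeric(logLik(g)),
               tolerance = 1e-10)
})

test_that("Laplace log-likelihood matches nested quadrature within 1%", {
  b <- tiny_bundle()
  spec <- gene_model_spec(fixed_variance = c(sib = 0.2, subj = 0.3,
                                             gene = 0.5))
  fit <- fit_gene_model(b, spec)
  exact <- loglik_oracle(b, fit, quadrature_points = 15)
  expect_lt(abs(fit$log_likelihood - exact) / abs(exact), 0.01)
  expect_lte(fit$log_likelihood, 0)
})

test_that("the quadrature oracle is self-consistent in its node count", {
  b <- tiny_bundle()
  spec <- gene_model_spec(fixed_variance = c(sib = 0.2, subj = 0.3,
                                             gene = 0.5))
  fit <- fit_gene_model(b, spec)
  l9 <- loglik_oracle(b, fit, 9)
  l15 <- loglik_oracle(b, fit, 15)
  l25 <- loglik_oracle(b, fit, 25)
  expect_lt(abs(l15 - l9), 1e-6)
  expect_lt(abs(l25 - l15), 1e-8)
})

test_that("the oracle refuses instances above its dimension cap", {
  b <- random_bundle(77, n = 12, G = 4, S_g = 2, missing_rate = 0)
  # one sibship of 2 subjects already has 1 + 2*(1+4) = 11 active dimensions
  spec <- gene_model_spec(fixed_variance = c(sib = .1, subj = .1, gene = .1))
  fit <- fit_gene_model(b, spec)
  expect_error(loglik_oracle(b, fit), class = "nestpath_size_error")
})

# --- empirical Bayes --------------------------------------------------------

test_that("a zero gene variance gives exactly zero EB estimates", {
  b <- tiny_bundle()
  fit <- fit_gene_model(b, gene_model_spec(
    fixed_variance = c(sib = 0.2, subj = 0.3, gene = 0)))
  eb <- empirical_bayes_estimates(fit)
  expect_identical(dim(eb), c(4L, 2L))
  expect_true(all(eb == 0))
})

test_that("EB estimates increase strictly with an added minor allele", {
  for (seed in 1:10) {
    b <- random_bundle(seed, n = 20, G = 2, S_g = 3, missing_rate = 0)
    fit <- fit_gene_model(b, gene_model_spec(
      fixed_variance = c(sib = 0.2, subj = 0.3, gene = 0.5)))
    eb <- empirical_bayes_estimates(fit)
    m <- b$genotypes$matrix
    cell <- which(m < 2)[1]
    jj <- (cell - 1) %% nrow(m) + 1
    ss <- (cell - 1) %/% nrow(m) + 1
    g <- unname(b$genotypes$gene_of_snp[ss])
    m2 <- m; m2[cell] <- m2[cell] + 1L
    b2 <- make_bundle(m2, b$study$data$sibship_id, b$genotypes$gene_of_snp)
    eb2 <- empirical_bayes_estimates(fit, newdata = b2)
    expect_gt(eb2[jj, g], eb[jj, g])
  }
})

test_that("the single-subject EB equals a 1-D grid-search posterior mode", {
  # one subject, one gene, three SNPs; subject and sibship variance 0 so the
  # conditional mode is a one-dimensional optimum
  m <- matrix(c(1L, 2L, 0L), nrow = 1,
              dimnames = list("solo", c("a", "b", "c")))
  b <- make_bundle(m, "f1", c(a = "g1", b = "g1", c = "g1"))
  s2g <- 0.5
  fit <- fit_gene_model(b, gene_model_spec(
    fixed_variance = c(sib = 0, subj = 0, gene = s2g)))
  beta <- fit$fixed_effects[colnames(m)]
  grid <- seq(-3, 3, by = 1e-4)
  post <- vapply(grid, function(bb)
    sum(dbinom(as.integer(m), 2, plogis(unname(beta) + bb), log = TRUE)) +
      dnorm(bb, 0, sqrt(s2g), log = TRUE), numeric(1))
  expect_equal(unname(fit$eb_matrix[1, 1]), grid[which.max(post)],
               tolerance = 1e-4)
})

test_that("EB columns are shrunk toward zero", {
  b <- random_bundle(21, n = 40, G = 3, S_g = 4, missing_rate = 0)
  fit <- fit_gene_model(b, gene_model_spec(
    fixed_variance = c(sib = 0.2, subj = 0.3, gene = 0.5)))
  eb <- empirical_bayes_estimates(fit)
  for (g in seq_len(ncol(eb)))
    expect_lt(abs(mean(eb[, g])), max(abs(eb)))
})

test_that("missing cells of one subject do not perturb others (singletons)", {
  b <- random_bundle(31, n = 15, G = 2, S_g = 3, missing_rate = 0)
  b$study$data$sibship_id <- sprintf("f%03d", 1:15)   # force singletons
  b <- dataset_bundle(b$study, b$genotypes)
  spec <- gene_model_spec(include_sibship_effect = FALSE,
                          fixed_variance = c(subj = 0.3, gene = 0.5))
  fit <- fit_gene_model(b, spec)
  m2 <- b$genotypes$matrix
  m2[3, ] <- NA                                       # blank one subject
  b2 <- make_bundle(m2, b$study$data$sibship_id, b$genotypes$gene_of_snp)
  eb2 <- empirical_bayes_estimates(fit, newdata = b2)
  expect_equal(eb2[-3, ], fit$eb_matrix[-3, ], tolerance = 1e-8)
  expect_equal(unname(eb2[3, ]), c(0, 0))             # no data -> prior mode
})

test_that("an unconverged fit refuses EB extraction", {
  b <- tiny_bundle()
  fit <- fit_gene_model(b, gene_model_spec(
    fixed_variance = c(sib = 0.2, subj = 0.3, gene = 0.5)))
  fit$converged <- FALSE
  expect_error(empirical_bayes_estimates(fit),
               class = "nestpath_convergence_error")
})

# --- structure and prediction ----------------------------------------------

test_that("eight genes with a genotype covariate give eight EB columns", {
  b <- random_bundle(55, n = 24, G = 8, S_g = 2, missing_rate = 0)
  b$study$geno_covariates <- "smoking"
  spec <- gene_model_spec(genotype_covariates = "smoking",
                          fixed_variance = c(sib = .1, subj = .2, gene = .3))
  fit <- fit_gene_model(b, spec)
  eb <- empirical_bayes_estimates(fit)
  expect_equal(ncol(eb), 8)
  expect_equal(nrow(eb), 24)
  expect_true("smoking" %in% names(fit$fixed_effects))
})

test_that("predicted genotype probabilities assemble the linear predictor", {
  # zero random effects: probability is the inverse-logit intercept
  m <- matrix(c(rep(1L, 20), rep(0L, 80)), ncol = 1,
              dimnames = list(sprintf("s%03d", 1:100), "snp1"))
  b <- make_bundle(m, sprintf("f%03d", 1:100), c(snp1 = "g1"))
  fit <- fit_gene_model(b, gene_model_spec(
    fixed_variance = c(sib = 0, subj = 0, gene = 0)))
  expect_equal(predict_genotype_probability(fit, "s001", "snp1"), 0.1,
               tolerance = 1e-6)

  # tiny fixture: matches hand assembly of fixed + conditional-mode terms
  bb <- tiny_bundle()
  fit2 <- fit_gene_model(bb, gene_model_spec(
    fixed_variance = c(sib = 0.2, subj = 0.3, gene = 0.5)))
  eta <- unname(fit2$fixed_effects[["g2_a"]]) +
    unname(fit2$b_sibship[["f1"]]) + unname(fit2$b_subject[["s2"]]) +
    fit2$eb_matrix["s2", "g2"]
  p <- predict_genotype_probability(fit2, "s2", "g2_a")
  expect_equal(p, plogis(eta), tolerance = 1e-10)
  expect_true(p > 0 && p < 1)
  expect_error(predict_genotype_probability(fit2, "nobody", "g2_a"),
               class = "nestpath_lookup_error")
})

test_that("variance components are recovered on nested simulated data", {
  # moderate-size check; the full-scale recovery study lives in the
  # acceptance suite
  sc <- simulation_scenario(n_sibships = 150, sibship_size = 4, G = 3,
                            S_g = 4, maf = c(.05, .1, .2, .4),
                            sigma2_sib = 0.2, sigma2_subj = 0.3,
                            sigma2_gene = 0.5)
  b <- filter_monomorphic(simulate_dataset(sc, 424))$bundle
  fit <- fit_gene_model(b)
  expect_true(fit$converged)
  vc <- fit$variance_components
  expect_true(all(vc >= 0))
  expect_gt(vc[["gene"]], 0.15)
  expect_lt(vc[["gene"]], 1.0)
  expect_gt(vc[["subj"]] + vc[["sib"]], 0.1)
})

test_that("a rank-deficient genotype design is rejected", {
  b <- random_bundle(91, n = 16, G = 2, S_g = 2, missing_rate = 0)
  b$study$data$dup <- b$study$data$smoking       # collinear covariate
  b$study$geno_covariates <- c("smoking", "dup")
  spec <- gene_model_spec(genotype_covariates = c("smoking", "dup"),
                          fixed_variance = c(subj = .1, gene = .1))
  expect_error(fit_gene_model(b, spec), class = "nestpath_design_error")
})
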