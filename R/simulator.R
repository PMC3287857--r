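#' Define a simulation scenario
#'
#' Describes a sibship-structured study generated from the same models the
#' package fits. Genotypes come from the nested random-effects binomial
#' model: per SNP, `w ~ Binomial(2, plogis(qlogis(maf) + covariate part +
#' b_sib + b_subj + b_gene))`. The drawn gene-within-subject effects are the
#' true gene burden scores; the phenotype is generated from the stage-2
#' model, quantitative (`y = x'beta + sum_g gamma_g b_g + interaction + u_sib
#' + e`) or binary (direct logistic with the same linear predictor plus a
#' baseline-prevalence intercept).
#'
#' @param n_sibships number of sibships.
#' @param sibship_size either a single integer (all sibships that size; 1 =
#'   unrelated subjects) or a named probability vector over sizes
#'   (e.g. `c("1"=.2,"2"=.3,...)`).
#' @param G number of genes; `S_g` SNPs per gene (scalar or length-G).
#' @param maf per-SNP minor allele frequencies, recycled gene by gene to
#'   `sum(S_g)` values; values in (0, 0.5].
#' @param sigma2_sib,sigma2_subj,sigma2_gene genotype-model variance
#'   components.
#' @param geno_covariate_effects named numeric of covariate effects on the
#'   genotype logit (covariates: `age`, `smoking`); default none.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param gamma true pathway effect per gene (length G; all zero = null).
#' @param beta0,beta_age,beta_smoking phenotype fixed effects.
#' @param interaction optional `list(gene = <index>, covariate = "smoking",
#'   effect = <numeric>)` gene-by-environment effect on the phenotype.
#' @param age_mean,age_sd,smoking_prev covariate generators (Age in years,
#'   normal; Smoking 0/1 Bernoulli).
#' @param sigma2_u,sigma2_e sibship and residual phenotype variances
#'   (quantitative traits).
#' @param prevalence baseline prevalence (binary traits; sets the intercept
#'   on the logit scale).
#' @param missing_rate fraction of genotype cells set missing at random.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_sibships = 150, sibship_size = 4,
                                G = 3, S_g = 4,
                                maf = c(0.05, 0.1, 0.2, 0.4),
                                sigma2_sib = 0.2, sigma2_subj = 0.3,
                                sigma2_gene = 0.5,
                                geno_covariate_effects = numeric(),
                                trait_type = c("quantitative", "binary"),
                                gamma = rep(0, G),
                                beta0 = 0, beta_age = 0.02,
                                beta_smoking = 0.5,
                                interaction = NULL,
                                age_mean = 50, age_sd = 10,
                                smoking_prev = 0.25,
                                sigma2_u = 0.5, sigma2_e = 1,
                                prevalence = 0.3,
                                missing_rate = 0) {
  trait_type <- match.arg(trait_type)
  S_g <- rep(S_g, length.out = G)
  maf <- rep(maf, length.out = sum(S_g))
  stopifnot(all(maf > 0), all(maf <= 0.5),
            sigma2_sib >= 0, sigma2_subj >= 0, sigma2_gene >= 0,
            sigma2_u >= 0, sigma2_e >= 0, length(gamma) == G,
            n_sibships >= 1, missing_rate >= 0, missing_rate < 1)
  if (length(sibship_size) == 1) {
    stopifnot(sibship_size >= 1)
  } else {
    stopifnot(!is.null(names(sibship_size)),
              abs(sum(sibship_size) - 1) < 1e-8)
  }
  stopifnot(all(names(geno_covariate_effects) %in% c("age", "smoking")))
  if (!is.null(interaction))
    stopifnot(interaction$covariate %in% c("age", "smoking"),
              interaction$gene %in% seq_len(G))
  structure(list(n_sibships = n_sibships, sibship_size = sibship_size,
                 G = G, S_g = S_g, maf = maf,
                 sigma2_sib = sigma2_sib, sigma2_subj = sigma2_subj,
                 sigma2_gene = sigma2_gene,
                 geno_covariate_effects = geno_covariate_effects,
                 trait_type = trait_type, gamma = gamma,
                 beta0 = beta0, beta_age = beta_age,
                 beta_smoking = beta_smoking, interaction = interaction,
                 age_mean = age_mean, age_sd = age_sd,
                 smoking_prev = smoking_prev,
                 sigma2_u = sigma2_u, sigma2_e = sigma2_e,
                 prevalence = prevalence, missing_rate = missing_rate),
            class = "simulation_scenario")
}

#' Simulate one dataset from a scenario
#'
#' Fully reproducible given `seed` (the caller's RNG state is untouched).
#' The drawn gene-within-subject effects (the generative analogue of the EB
#' summaries) are attached as `attr(bundle, "truth")$b_gene`.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed.
#' @return A [dataset_bundle()] with phenotype column `y` and covariates
#'   `age`, `smoking`.
#' @export
simulate_dataset <- function(scenario, seed) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  with_seed(seed, {
    sizes <- if (length(sc$sibship_size) == 1)
      rep(sc$sibship_size, sc$n_sibships)
    else
      sample(as.integer(names(sc$sibship_size)), sc$n_sibships,
             replace = TRUE, prob = sc$sibship_size)
    N <- sum(sizes)
    sib_of_subj <- rep(seq_len(sc$n_sibships), sizes)
    subject_id <- sprintf("sub%05d", seq_len(N))
    sibship_id <- sprintf("fam%04d", sib_of_subj)

    age <- rnorm(N, sc$age_mean, sc$age_sd)
    smoking <- rbinom(N, 1, sc$smoking_prev)

    b_sib <- rnorm(sc$n_sibships, 0, sqrt(sc$sigma2_sib))
    b_subj <- rnorm(N, 0, sqrt(sc$sigma2_subj))
    b_gene <- matrix(rnorm(N * sc$G, 0, sqrt(sc$sigma2_gene)), N, sc$G)

    cov_eta <- rep(0, N)
    for (cv in names(sc$geno_covariate_effects))
      cov_eta <- cov_eta +
        sc$geno_covariate_effects[[cv]] * get(cv)

    S_tot <- sum(sc$S_g)
    gene_of_col <- rep(seq_len(sc$G), sc$S_g)
    genes <- paste0("g", seq_len(sc$G))
    snp_ids <- paste0(genes[gene_of_col], "_s",
                      unlist(lapply(sc$S_g, seq_len)))
    m <- matrix(NA_integer_, N, S_tot, dimnames = list(subject_id, snp_ids))
    for (s in seq_len(S_tot)) {
      g <- gene_of_col[s]
      eta <- qlogis(sc$maf[s]) + cov_eta + b_sib[sib_of_subj] + b_subj +
        b_gene[, g]
      m[, s] <- rbinom(N, 2, plogis(eta))
    }
    if (sc$missing_rate > 0) {
      drop <- runif(N * S_tot) < sc$missing_rate
      m[drop] <- NA_integer_
    }

    lin <- sc$beta0 + sc$beta_age * age + sc$beta_smoking * smoking +
      as.numeric(b_gene %*% sc$gamma)
    if (!is.null(sc$interaction))
      lin <- lin + sc$interaction$effect *
        b_gene[, sc$interaction$gene] * get(sc$interaction$covariate)

    if (sc$trait_type == "quantitative") {
      u <- rnorm(sc$n_sibships, 0, sqrt(sc$sigma2_u))
      y <- lin + u[sib_of_subj] + rnorm(N, 0, sqrt(sc$sigma2_e))
    } else {
      eta_y <- qlogis(sc$prevalence) + lin
      for (attempt in seq_len(10)) {
        y <- rbinom(N, 1, plogis(eta_y))
        if (length(unique(y)) > 1) break
        np_warn("degenerate binary trait draw; resampling",
                "nestpath_resample_warning")
      }
      if (length(unique(y)) == 1)
        np_stop("binary trait degenerate after 10 resampling attempts",
                "nestpath_degenerate_error")
    }

    dat <- data.frame(subject_id = subject_id, sibship_id = sibship_id,
                      age = age, smoking = smoking, y = y,
                      stringsAsFactors = FALSE)
    study <- study_frame(dat, phenotypes = "y",
                         pheno_covariates = c("age", "smoking"),
                         geno_covariates =
                           names(sc$geno_covariate_effects) %||% character())
    gb <- genotype_block(m, setNames(genes[gene_of_col], snp_ids),
                         minor_allele_coded = TRUE)
    bundle <- dataset_bundle(study, gb,
                             sprintf("simulate_dataset(seed=%d)", seed))
    attr(bundle, "truth") <- list(b_sib = b_sib, b_subj = b_subj,
                                  b_gene = `dimnames<-`(
                                    b_gene, list(subject_id, genes)))
    bundle
  })
}

#' Monte-Carlo operating characteristics of the two-stage test
#'
#' Repeatedly simulates a scenario, runs the full two-stage analysis
#' (monomorphic filter, stage-1 genotype model, EB extraction, stage-2
#' phenotype model, G-df pathway Wald test) and reports the rejection
#' fraction at `alpha`. Per-replicate seeds are derived from the global seed
#' by a counter scheme, so replicates are independent and order-insensitive.
#' Replicates whose fits fail or do not converge are excluded from the
#' denominator (their count is reported); more than 20% failures aborts.
#'
#' @param scenario a [simulation_scenario()].
#' @param n_replicates number of Monte-Carlo replicates (>= 50 for stable
#'   rate estimates).
#' @param alpha nominal level.
#' @param seed global integer seed.
#' @param gene_spec optional [gene_model_spec()] override for the stage-1
#'   fit.
#' @return An object of class `operating_characteristics`: rejection rates
#'   (pathway and per gene), Monte-Carlo standard error, per-replicate
#'   records.
#' @export
run_operating_characteristics <- function(scenario, n_replicates = 200,
                                          alpha = 0.05, seed = 1,
                                          gene_spec = NULL) {
  stopifnot(inherits(scenario, "simulation_scenario"),
            alpha > 0, alpha <= 1)
  if (n_replicates < 50)
    np_warn("fewer than 50 replicates: rate estimates will be noisy",
            "nestpath_small_sample_warning")
  recs <- vector("list", n_replicates)
  gene_p <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    seed_r <- derive_seed(seed, r)
    res <- tryCatch(analyze_replicate(scenario, seed_r, gene_spec),
                    error = function(e) NULL)
    if (is.null(res)) {
      recs[[r]] <- data.frame(replicate = r, seed = seed_r,
                              stat = NA_real_, p = NA_real_,
                              converged = FALSE)
    } else {
      recs[[r]] <- data.frame(replicate = r, seed = seed_r,
                              stat = res$report$pathway_stat,
                              p = res$report$pathway_p, converged = TRUE)
      gene_p[[r]] <- setNames(res$report$gene_results$p,
                              res$report$gene_results$gene)
    }
  }
  records <- do.call(rbind, recs)
  n_fail <- sum(!records$converged)
  if (n_fail > 0.2 * n_replicates)
    np_stop(sprintf("%d/%d replicates failed to converge", n_fail,
                    n_replicates),
            "nestpath_convergence_error")
  ok <- records$converged
  rate <- mean(records$p[ok] < alpha)
  all_genes <- sort(unique(unlist(lapply(gene_p, names))))
  gene_rates <- vapply(all_genes, function(g) {
    ps <- unlist(lapply(gene_p, function(v) v[g]))
    mean(ps < alpha, na.rm = TRUE)
  }, numeric(1))
  structure(list(n_replicates = n_replicates, alpha = alpha,
                 n_failed = n_fail,
                 rejection_rate_pathway = rate,
                 rejection_rate_genes = gene_rates,
                 mc_se = sqrt(rate * (1 - rate) / sum(ok)),
                 records = records),
            class = "operating_characteristics")
}

# the per-replicate analysis: simulate + two-stage pipeline
analyze_replicate <- function(scenario, seed_r, gene_spec = NULL) {
  bundle <- simulate_dataset(scenario, seed_r)
  filt <- filter_monomorphic(bundle)
  gspec <- gene_spec %||% gene_model_spec(
    genotype_covariates = names(scenario$geno_covariate_effects) %||%
      character())
  gfit <- fit_gene_model(filt$bundle, gspec)
  eb <- empirical_bayes_estimates(gfit)
  pspec <- phenotype_model_spec(
    trait_name = "y", trait_type = scenario$trait_type,
    covariate_names = c("age", "smoking"))
  pfit <- if (scenario$trait_type == "binary")
    fit_gee(filt$bundle$study, eb, pspec)
  else fit_lmm(filt$bundle$study, eb, pspec)
  report <- pathway_wald(pfit)
  list(bundle = filt$bundle, gene_fit = gfit, pheno_fit = pfit,
       report = report)
}

#' @exportS3Method base::print
print.operating_characteristics <- function(x, ...) {
  cat(sprintf(paste0("operating_characteristics: %d replicates ",
                     "(%d failed), alpha = %.3f\n"),
              x$n_replicates, x$n_failed, x$alpha))
  cat(sprintf("  pathway rejection rate: %.3f (MC SE %.3f)\n",
              x$rejection_rate_pathway, x$mc_se))
  invisible(x)
}
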