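#' Pathway-level Wald chi-square test
#'
#' Tests the null hypothesis of no pathway effect, `H0: gamma_1 = ... =
#' gamma_G = 0`, with the Wald statistic `W = gamma' V^-1 gamma` compared to
#' a chi-square distribution with `G` degrees of freedom. The covariance is
#' the one carried by the fit: model-based for the linear mixed model,
#' robust sandwich for the GEE. Interaction coefficients are not part of the
#' pathway null and are tested separately (set `include_interactions = TRUE`
#' for a joint G+k df test).
#'
#' @param fit a [fit_lmm()] or [fit_gee()] result.
#' @param gene_terms gene labels to test; `NULL` = all genes in the fit.
#' @param include_interactions include interaction coefficients in the null.
#' @param alpha nominal level recorded in the report.
#' @param singular one of `"error"` (default) or `"pseudo_inverse"`; how a
#'   singular covariance sub-block is handled (pseudo-inverse uses the
#'   effective rank as degrees of freedom and flags the report).
#' @return An object of class `test_report` with `pathway_stat`,
#'   `pathway_df`, `pathway_p`, `gene_results`, `interaction_results`.
#' @export
pathway_wald <- function(fit, gene_terms = NULL, include_interactions = FALSE,
                         alpha = 0.05, singular = c("error",
                                                    "pseudo_inverse")) {
  stopifnot(inherits(fit, "phenotype_fit"))
  singular <- match.arg(singular)
  tm <- fit$term_map
  genes <- gene_terms %||% names(tm$genes)
  missing_terms <- setdiff(genes, names(tm$genes))
  if (length(missing_terms))
    np_stop(paste("gene terms not in fit:",
                  paste(missing_terms, collapse = ", ")),
            "nestpath_lookup_error")
  cols <- unname(tm$genes[genes])
  if (include_interactions) cols <- c(cols, unname(tm$interactions))

  gam <- fit$coefficients[cols]
  V <- fit$covariance[cols, cols, drop = FALSE]
  df <- length(cols)
  flag <- NULL
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-10) {
    if (singular == "error")
      np_stop("singular covariance of the tested coefficients",
              "nestpath_singular_error")
    W <- as.numeric(gam %*% pseudo_inverse(V) %*% gam)
    df <- sum(ev > max(ev) * 1e-10)
    flag <- "pseudo-inverse covariance; df = effective rank"
    np_warn(flag, "nestpath_singular_warning")
  } else {
    W <- as.numeric(gam %*% solve(V, gam))
  }
  W <- max(W, 0)
  structure(list(pathway_stat = W, pathway_df = df,
                 pathway_p = pchisq(W, df, lower.tail = FALSE),
                 gene_results = gene_tests(fit, genes),
                 interaction_results = interaction_results(fit),
                 alpha = alpha,
                 method_notes = c(
                   sprintf("covariance: %s",
                           if (fit$model == "gee") "robust sandwich"
                           else "model-based"),
                   flag)),
            class = "test_report")
}

pseudo_inverse <- function(V, tol = 1e-10) {
  e <- eigen(V, symmetric = TRUE)
  keep <- e$values > max(e$values) * tol
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

#' Gene-level conditional Wald tests
#'
#' One-degree-of-freedom Wald test of each gene's pathway coefficient
#' `gamma_g = 0` from the joint stage-2 fit, i.e. conditional on the EB
#' terms of the remaining genes.
#'
#' @inheritParams pathway_wald
#' @return data.frame with columns `gene`, `estimate`, `se`, `stat`, `p`.
#' @export
gene_tests <- function(fit, gene_terms = NULL) {
  stopifnot(inherits(fit, "phenotype_fit"))
  tm <- fit$term_map
  genes <- gene_terms %||% names(tm$genes)
  missing_terms <- setdiff(genes, names(tm$genes))
  if (length(missing_terms))
    np_stop(paste("gene terms not in fit:",
                  paste(missing_terms, collapse = ", ")),
            "nestpath_lookup_error")
  cols <- unname(tm$genes[genes])
  est <- fit$coefficients[cols]
  se <- sqrt(diag(fit$covariance)[cols])
  stat <- (est / se)^2
  data.frame(gene = genes, estimate = unname(est), se = unname(se),
             stat = unname(stat),
             p = pchisq(unname(stat), 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

interaction_results <- function(fit) {
  tm <- fit$term_map
  if (!length(tm$interactions))
    return(data.frame(term = character(), estimate = numeric(),
                      se = numeric(), stat = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  cols <- unname(tm$interactions)
  est <- fit$coefficients[cols]
  se <- sqrt(diag(fit$covariance)[cols])
  stat <- (est / se)^2
  data.frame(term = names(tm$interactions), estimate = unname(est),
             se = unname(se), stat = unname(stat),
             p = pchisq(unname(stat), 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Gene-by-environment interaction Wald test
#'
#' One-degree-of-freedom Wald test of a single EB-by-covariate interaction
#' coefficient (e.g. a gene's burden by smoking status).
#'
#' @param fit a [fit_lmm()] or [fit_gee()] result.
#' @param term length-2 character vector `c(gene, covariate)`.
#' @return one-row data.frame with `term`, `estimate`, `se`, `stat`, `p`.
#' @export
interaction_test <- function(fit, term) {
  stopifnot(inherits(fit, "phenotype_fit"))
  key <- paste0(term[1], ":", term[2])
  res <- interaction_results(fit)
  row <- res[res$term == key, , drop = FALSE]
  if (!nrow(row))
    np_stop(paste("interaction term not in fit:", key),
            "nestpath_lookup_error")
  row
}

#' @exportS3Method base::print
print.test_report <- function(x, ...) {
  cat(sprintf("Pathway Wald test: W = %.4f on %d df, p = %s\n",
              x$pathway_stat, x$pathway_df, fmt_p(x$pathway_p)))
  if (nrow(x$gene_results)) {
    cat("Gene-level (conditional 1-df) tests:\n")
    gr <- x$gene_results
    for (k in seq_len(nrow(gr)))
      cat(sprintf("  %-12s est = %8.4f  se = %7.4f  p = %s\n",
                  gr$gene[k], gr$estimate[k], gr$se[k], fmt_p(gr$p[k])))
  }
  if (nrow(x$interaction_results)) {
    ir <- x$interaction_results
    for (k in seq_len(nrow(ir)))
      cat(sprintf("  %-12s est = %8.4f  se = %7.4f  p = %s (interaction)\n",
                  ir$term[k], ir$estimate[k], ir$se[k], fmt_p(ir$p[k])))
  }
  cat("  notes:", paste(x$method_notes, collapse = "; "), "\n")
  invisible(x)
}

#' One-df collapsed rare-variant pathway test
#'
#' Pools all rare variants (minor allele frequency below `maf_threshold`)
#' across all genes of the pathway into a single pseudo-gene, fits the
#' stage-1 model to obtain one EB burden column, enters it into the
#' phenotype model, and returns the 1-df Wald test. More powerful than the
#' G-df pathway test when many genes carry weak rare-variant signal, but the
#' within-gene structure is ignored, so gene-specific gene-by-environment
#' interactions cannot be modelled in this mode.
#'
#' @param bundle a [dataset_bundle()] (monomorphic SNPs already removed).
#' @param pheno_spec a [phenotype_model_spec()] (its `gene_terms` and
#'   `interaction_terms` are ignored; the single burden term is tested).
#' @param gene_spec a [gene_model_spec()] for the stage-1 refit.
#' @param maf_threshold rare-variant MAF cutoff (default 0.05).
#' @return An object of class `test_report` with `pathway_df = 1`.
#' @export
collapsed_rare_test <- function(bundle, pheno_spec,
                                gene_spec = gene_model_spec(),
                                maf_threshold = 0.05) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  maf <- coded_allele_freq(bundle$genotypes$matrix)
  rare <- names(maf)[!is.na(maf) & maf < maf_threshold]
  if (!length(rare))
    np_stop("no rare variants below the MAF threshold",
            "nestpath_empty_set_error")
  m <- bundle$genotypes$matrix[, rare, drop = FALSE]
  gb <- genotype_block(m, setNames(rep("rare_burden", length(rare)), rare),
                       bundle$genotypes$minor_allele_coded)
  collapsed <- dataset_bundle(bundle$study, gb,
                              paste0(bundle$provenance,
                                     "; collapsed rare variants (MAF < ",
                                     maf_threshold, ")"))
  gfit <- fit_gene_model(collapsed, gene_spec)
  eb <- empirical_bayes_estimates(gfit)
  ps <- pheno_spec
  ps$gene_terms <- "rare_burden"
  ps$interaction_terms <- list()
  pfit <- if (identical(ps$trait_type, "binary") ||
              (is.null(ps$trait_type) &&
               is_binary_trait(bundle$study, ps$trait_name)))
    fit_gee(bundle$study, eb, ps) else fit_lmm(bundle$study, eb, ps)
  pathway_wald(pfit, "rare_burden")
}
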