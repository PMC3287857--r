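#' Configuration for an end-to-end two-stage run
#'
#' Either file paths (`genotype_path`, `pedigree_path`, `phenotype_path`,
#' `gene_map_path`, `dialect`) or an in-memory `bundle` must be supplied.
#'
#' @param genotype_path,pedigree_path,phenotype_path,gene_map_path input
#'   files (see [read_dataset()]).
#' @param dialect genotype dialect for [read_dataset()].
#' @param bundle optional in-memory [dataset_bundle()] (overrides paths).
#' @param trait phenotype column to analyze.
#' @param trait_type `"quantitative"`, `"binary"` or `NULL` (auto-detect).
#' @param covariates stage-2 covariate names.
#' @param geno_covariates stage-1 covariate names.
#' @param interactions list of `c(gene, covariate)` pairs.
#' @param gene_spec a [gene_model_spec()].
#' @param out_dir output directory (`NULL`: no files written).
#' @param seed integer seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(genotype_path = NULL, pedigree_path = NULL,
                       phenotype_path = NULL, gene_map_path = NULL,
                       dialect = "tsv", bundle = NULL,
                       trait = "y", trait_type = NULL,
                       covariates = c("age", "smoking"),
                       geno_covariates = character(),
                       interactions = list(),
                       gene_spec = NULL,
                       out_dir = NULL, seed = 1, log_level = "info") {
  if (is.null(bundle)) {
    paths <- c(genotype_path, pedigree_path, phenotype_path, gene_map_path)
    if (length(paths) < 4)
      np_stop("either a bundle or all four input paths are required",
              "nestpath_validation_error")
    for (p in paths)
      if (!file.exists(p))
        np_stop(paste("file not found:", p), "nestpath_validation_error")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  structure(list(genotype_path = genotype_path,
                 pedigree_path = pedigree_path,
                 phenotype_path = phenotype_path,
                 gene_map_path = gene_map_path, dialect = dialect,
                 bundle = bundle, trait = trait, trait_type = trait_type,
                 covariates = covariates, geno_covariates = geno_covariates,
                 interactions = interactions, gene_spec = gene_spec,
                 out_dir = out_dir, seed = seed, log_level = log_level),
            class = "run_config")
}

#' Run the two-stage pathway analysis end to end
#'
#' read -> monomorphic filter -> stage-1 genotype model -> empirical Bayes
#' extraction -> stage-2 phenotype model -> pathway / gene / interaction
#' Wald tests. The stage-1 fit is independent of the trait, so the returned
#' `gene_fit` can be reused across traits of the same dataset. If
#' `config$out_dir` is set, fit summaries (JSON), the EB matrix (TSV), the
#' test report (JSON + TSV) and a structured log are written; every output
#' records the hash of the configuration that produced it.
#'
#' @param config a [run_config()].
#' @return list with `gene_fit`, `pheno_fit`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config[setdiff(names(config), "bundle")])
  log_lines <- c(sprintf("nestpath %s | config %s | seed %d",
                         as.character(utils::packageVersion("nestpath")),
                         hash, config$seed))
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (identical(config$log_level, "info")) message("[nestpath] ", line)
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      np_stop(sprintf("[stage: %s] %s", label, conditionMessage(e)),
              "nestpath_pipeline_error")
    })
  }

  bundle <- stage("read", {
    if (!is.null(config$bundle)) config$bundle
    else read_dataset(config$genotype_path, config$pedigree_path,
                      config$phenotype_path, config$gene_map_path,
                      dialect = config$dialect,
                      pheno_covariates = config$covariates,
                      geno_covariates = config$geno_covariates)
  })
  say("read: %d subjects, %d SNPs, %d genes", n_subjects(bundle$study),
      ncol(bundle$genotypes$matrix),
      length(genes_of(bundle$genotypes)))

  filt <- stage("filter", filter_monomorphic(bundle))
  say("filter: removed %d monomorphic SNPs", length(filt$removed_snp_ids))
  bundle <- filt$bundle

  gspec <- config$gene_spec %||%
    gene_model_spec(genotype_covariates = config$geno_covariates)
  gfit <- stage("gene_model", fit_gene_model(bundle, gspec))
  say("stage 1: Laplace logLik %.4f, variance components %s, %s",
      gfit$log_likelihood,
      paste(sprintf("%.4f", gfit$variance_components), collapse = "/"),
      if (gfit$converged) "converged" else "NOT converged")

  eb <- stage("empirical_bayes", empirical_bayes_estimates(gfit))

  trait_type <- config$trait_type %||%
    (if (is_binary_trait(bundle$study, config$trait)) "binary"
     else "quantitative")
  pspec <- phenotype_model_spec(trait_name = config$trait,
                                trait_type = trait_type,
                                covariate_names = config$covariates,
                                interaction_terms = config$interactions)
  pfit <- stage("phenotype_model", {
    if (trait_type == "binary") fit_gee(bundle$study, eb, pspec)
    else fit_lmm(bundle$study, eb, pspec)
  })
  say("stage 2 (%s, %s): %d coefficients, %d clusters", trait_type,
      pfit$model, length(pfit$coefficients), pfit$n_clusters)

  report <- stage("tests", pathway_wald(pfit))
  say("pathway: W = %.4f on %d df, p = %s", report$pathway_stat,
      report$pathway_df, fmt_p(report$pathway_p))

  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    write_gene_model_fit(gfit, file.path(od, "gene_fit.json"),
                         file.path(od, "eb.tsv"), hash)
    jsonlite::write_json(serialize_pheno_fit(pfit, hash),
                         file.path(od, "pheno_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(serialize_report(report, hash),
                         file.path(od, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    render_report(report, style = "tsv",
                  path = file.path(od, "report.tsv"), config_hash = hash)
    writeLines(log_lines, file.path(od, "run.log"))
  }
  list(gene_fit = gfit, pheno_fit = pfit, report = report)
}

write_gene_model_fit <- function(gfit, json_path, eb_path, hash = "") {
  jsonlite::write_json(
    list(config_hash = hash,
         fixed_effects = as.list(gfit$fixed_effects),
         variance_components = as.list(gfit$variance_components),
         log_likelihood = gfit$log_likelihood,
         converged = gfit$converged,
         n_iterations = gfit$n_iterations,
         eb_sidecar = basename(eb_path)),
    json_path, auto_unbox = TRUE, digits = NA)
  eb <- data.frame(subject_id = rownames(gfit$eb_matrix),
                   gfit$eb_matrix, check.names = FALSE)
  write_tsv(eb, eb_path)
}

serialize_pheno_fit <- function(pfit, hash = "") {
  list(config_hash = hash, model = pfit$model,
       coefficients = as.list(pfit$coefficients),
       covariance = unname(apply(pfit$covariance, 1, as.list)),
       sibship_variance = pfit$sibship_variance,
       residual_variance = pfit$residual_variance,
       working_correlation = pfit$working_correlation,
       scale = pfit$scale, n_clusters = pfit$n_clusters,
       converged = pfit$converged)
}

serialize_report <- function(report, hash = "") {
  list(config_hash = hash,
       pathway = list(stat = report$pathway_stat, df = report$pathway_df,
                      p = report$pathway_p),
       genes = report$gene_results,
       interactions = report$interaction_results,
       alpha = report$alpha, method_notes = report$method_notes)
}

#' Render a test report as a table
#'
#' Rows: one per gene, one per interaction term, one for the pathway test;
#' columns: term, estimate, SE, df, p. The TSV style writes plain numeric
#' columns (parse-back safe); the markdown style formats p-values below
#' 1e-4 in scientific notation such as `4.9 x 10^-10`.
#'
#' @param report a `test_report` from [pathway_wald()].
#' @param style `"tsv"` or `"markdown"`.
#' @param path output file (`NULL` returns the lines invisibly without
#'   writing).
#' @param config_hash optional provenance string included as a comment.
#' @return invisibly, the character vector of lines.
#' @export
render_report <- function(report, style = c("tsv", "markdown"),
                          path = NULL, config_hash = NULL) {
  stopifnot(inherits(report, "test_report"))
  style <- match.arg(style)
  gr <- report$gene_results
  ir <- report$interaction_results
  tab <- rbind(
    data.frame(term = gr$gene, estimate = gr$estimate, se = gr$se,
               df = 1, p = gr$p, stringsAsFactors = FALSE),
    if (nrow(ir)) data.frame(term = paste0("interaction:", ir$term),
                             estimate = ir$estimate, se = ir$se, df = 1,
                             p = ir$p, stringsAsFactors = FALSE),
    data.frame(term = "pathway", estimate = NA_real_, se = NA_real_,
               df = report$pathway_df, p = report$pathway_p,
               stringsAsFactors = FALSE))
  if (style == "tsv") {
    lines <- c(if (!is.null(config_hash))
                 paste0("# config_hash: ", config_hash),
               paste(colnames(tab), collapse = "\t"),
               vapply(seq_len(nrow(tab)), function(k)
                 paste(c(tab$term[k],
                         format(tab$estimate[k], digits = 10),
                         format(tab$se[k], digits = 10),
                         tab$df[k],
                         format(tab$p[k], digits = 10)),
                       collapse = "\t"), character(1)))
  } else {
    sci <- function(p) {
      if (is.na(p)) return("")
      if (p >= 1e-4) return(sprintf("%.4f", p))
      e <- floor(log10(p))
      sprintf("%.1f x 10^%d", p / 10^e, e)
    }
    num <- function(v) ifelse(is.na(v), "", sprintf("%.4f", v))
    lines <- c(if (!is.null(config_hash))
                 paste0("<!-- config_hash: ", config_hash, " -->"),
               "| term | estimate | SE | df | p |",
               "|---|---|---|---|---|",
               vapply(seq_len(nrow(tab)), function(k)
                 sprintf("| %s | %s | %s | %d | %s |", tab$term[k],
                         num(tab$estimate[k]), num(tab$se[k]), tab$df[k],
                         sci(tab$p[k])), character(1)))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
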