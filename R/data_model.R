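#' Study frame: subjects, sibship membership, covariates and phenotypes
#'
#' The subject-level table of a pathway study. Each subject belongs to exactly
#' one sibship (cluster); singleton sibships encode unrelated subjects.
#' Phenotypes are quantitative (real) or binary (0/1, NA allowed); covariates
#' are split into the set entering the phenotype models (e.g. Age, Smoking)
#' and the set entering the genotype model (e.g. Smoking).
#'
#' @param data data.frame with at least `subject_id` and `sibship_id` columns
#'   (coerced to character), plus covariate and phenotype columns.
#' @param phenotypes character vector of phenotype column names.
#' @param pheno_covariates character vector of covariate columns for the
#'   phenotype models.
#' @param geno_covariates character vector of covariate columns for the
#'   genotype (gene) model.
#' @return An object of class `study_frame`.
#' @export
study_frame <- function(data, phenotypes = character(),
                        pheno_covariates = character(),
                        geno_covariates = character()) {
  if (!is.data.frame(data))
    np_stop("`data` must be a data.frame", "nestpath_format_error")
  need <- c("subject_id", "sibship_id")
  if (!all(need %in% names(data)))
    np_stop("`data` must contain subject_id and sibship_id columns",
            "nestpath_format_error")
  data$subject_id <- as.character(data$subject_id)
  data$sibship_id <- as.character(data$sibship_id)
  if (anyDuplicated(data$subject_id))
    np_stop("subject_id values must be unique", "nestpath_format_error")
  if (anyNA(data$subject_id) || anyNA(data$sibship_id))
    np_stop("subject_id/sibship_id must be non-missing",
            "nestpath_format_error")
  all_cols <- c(phenotypes, pheno_covariates, geno_covariates)
  missing_cols <- setdiff(all_cols, names(data))
  if (length(missing_cols))
    np_stop(paste("columns not in data:", paste(missing_cols, collapse = ", ")),
            "nestpath_format_error")
  for (ph in phenotypes) {
    v <- data[[ph]]
    if (!is.numeric(v))
      np_stop(sprintf("phenotype '%s' must be numeric", ph),
              "nestpath_format_error")
  }
  rownames(data) <- NULL
  structure(list(data = data,
                 phenotypes = phenotypes,
                 pheno_covariates = pheno_covariates,
                 geno_covariates = geno_covariates),
            class = "study_frame")
}

#' @exportS3Method base::print
print.study_frame <- function(x, ...) {
  sizes <- table(x$data$sibship_id)
  cat(sprintf("study_frame: %d subjects in %d sibships (sizes %d-%d)\n",
              nrow(x$data), length(sizes), min(sizes), max(sizes)))
  cat("  phenotypes:       ", paste(x$phenotypes, collapse = ", "), "\n")
  cat("  pheno covariates: ", paste(x$pheno_covariates, collapse = ", "), "\n")
  cat("  geno covariates:  ", paste(x$geno_covariates, collapse = ", "), "\n")
  invisible(x)
}

n_subjects <- function(study) nrow(study$data)

# TRUE if a phenotype column is binary (all non-missing values in {0,1})
is_binary_trait <- function(study, trait) {
  v <- study$data[[trait]]
  all(v[!is.na(v)] %in% c(0, 1))
}

#' Genotype block: additive genotype matrix plus SNP-to-gene map
#'
#' Genotypes are coded 0/1/2 (count of the coded allele) with NA for missing.
#' Every SNP column maps to exactly one gene. After minor-allele orientation
#' (see [read_dataset()]) codes count the minor allele.
#'
#' @param matrix integer matrix, subjects x SNPs, entries in \{0,1,2,NA\};
#'   rownames are subject ids, colnames SNP ids.
#' @param gene_of_snp named character vector mapping snp_id -> gene label.
#' @param minor_allele_coded logical flag: codes count minor alleles.
#' @return An object of class `genotype_block`.
#' @export
genotype_block <- function(matrix, gene_of_snp, minor_allele_coded = FALSE) {
  m <- as.matrix(matrix)
  if (is.null(colnames(m)))
    np_stop("genotype matrix must have SNP ids as colnames",
            "nestpath_format_error")
  bad <- !(m %in% c(0L, 1L, 2L) | is.na(m))
  if (any(bad))
    np_stop("genotype codes must be 0, 1, 2 or missing",
            "nestpath_format_error")
  storage.mode(m) <- "integer"
  unmapped <- setdiff(colnames(m), names(gene_of_snp))
  if (length(unmapped))
    np_stop(paste("SNPs without gene assignment:",
                  paste(unmapped, collapse = ", ")),
            "nestpath_mapping_error")
  gene_of_snp <- gene_of_snp[colnames(m)]
  structure(list(matrix = m,
                 snp_id = colnames(m),
                 gene_of_snp = gene_of_snp,
                 minor_allele_coded = isTRUE(minor_allele_coded)),
            class = "genotype_block")
}

#' @exportS3Method base::print
print.genotype_block <- function(x, ...) {
  cat(sprintf("genotype_block: %d subjects x %d SNPs in %d genes\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$gene_of_snp))))
  invisible(x)
}

genes_of <- function(gb) unique(unname(gb$gene_of_snp))

# per-SNP coded-allele frequency among non-missing entries
coded_allele_freq <- function(m) {
  colSums(m, na.rm = TRUE) / (2 * colSums(!is.na(m)))
}

#' Dataset bundle: aligned study frame + genotype block
#'
#' @param study a [study_frame()].
#' @param genotypes a [genotype_block()] whose rows align one-to-one (by
#'   subject id) with `study`.
#' @param provenance free-text description of the data source.
#' @return An object of class `dataset_bundle`.
#' @export
dataset_bundle <- function(study, genotypes, provenance = "") {
  stopifnot(inherits(study, "study_frame"),
            inherits(genotypes, "genotype_block"))
  ids <- study$data$subject_id
  gids <- rownames(genotypes$matrix)
  if (is.null(gids))
    np_stop("genotype matrix must carry subject ids as rownames",
            "nestpath_alignment_error")
  if (!setequal(ids, gids) || length(ids) != length(gids))
    np_stop("genotype subjects do not match study subjects",
            "nestpath_alignment_error")
  genotypes$matrix <- genotypes$matrix[ids, , drop = FALSE]
  structure(list(study = study, genotypes = genotypes,
                 provenance = provenance),
            class = "dataset_bundle")
}

#' @exportS3Method base::print
print.dataset_bundle <- function(x, ...) {
  print(x$study)
  print(x$genotypes)
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Remove SNPs without variation
#'
#' Drops genotype columns that are constant across all non-missing entries
#' (monomorphic in the sample); a pathway restricted to families typically
#' retains only the subset of its SNPs that vary there. Genes left without
#' SNPs are dropped from the gene map.
#'
#' @param bundle a [dataset_bundle()].
#' @return list with elements `bundle` (filtered) and `removed_snp_ids`.
#' @export
filter_monomorphic <- function(bundle) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  m <- bundle$genotypes$matrix
  mono <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    v <- v[!is.na(v)]
    length(v) == 0L || length(unique(v)) == 1L
  }, logical(1))
  removed <- colnames(m)[mono]
  if (all(mono))
    np_stop("all SNPs are monomorphic: empty pathway",
            "nestpath_empty_pathway_error")
  keep <- m[, !mono, drop = FALSE]
  gb <- genotype_block(keep,
                       bundle$genotypes$gene_of_snp[colnames(keep)],
                       bundle$genotypes$minor_allele_coded)
  out <- dataset_bundle(bundle$study, gb, bundle$provenance)
  list(bundle = out, removed_snp_ids = removed)
}
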