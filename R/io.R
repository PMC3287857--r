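#' Read a pathway study dataset from standard files
#'
#' Assembles a validated [dataset_bundle()] from a genotype file (TSV matrix,
#' PLINK additive `.raw` recode, or VCF), a pedigree/sibship file (two-column
#' TSV or PLINK `.fam`), a phenotype + covariate TSV and a SNP-to-gene map
#' TSV (columns `snp_id`, `gene`). Pedigrees with parent links are collapsed
#' to sibship clusters. After reading, genotype codes are oriented to count
#' the minor allele: any SNP whose coded-allele frequency exceeds 0.5 is
#' flipped (w -> 2 - w), and the flips are recorded in the bundle provenance;
#' frequency exactly 0.5 keeps the original orientation.
#'
#' @param genotype_path path to the genotype file.
#' @param pedigree_path path to the pedigree/sibship file.
#' @param phenotype_path path to the phenotype/covariate TSV (must contain a
#'   `subject_id` column; missing values written as `NA`).
#' @param gene_map_path path to the SNP-to-gene map TSV.
#' @param dialect one of `"tsv"`, `"plink_raw"`, `"vcf"`.
#' @param phenotypes,pheno_covariates,geno_covariates character vectors
#'   naming phenotype and covariate columns of the phenotype table. If
#'   `roles_path` is given these are read from it; otherwise unassigned
#'   numeric columns default to phenotypes.
#' @param roles_path optional JSON file (as written by [write_dataset()])
#'   recording the column roles.
#' @return A [dataset_bundle()], genotypes oriented to minor alleles.
#' @seealso [write_dataset()], [filter_monomorphic()]
#' @export
read_dataset <- function(genotype_path, pedigree_path, phenotype_path,
                         gene_map_path,
                         dialect = c("tsv", "plink_raw", "vcf"),
                         phenotypes = NULL, pheno_covariates = NULL,
                         geno_covariates = NULL, roles_path = NULL) {
  dialect <- match.arg(dialect)
  for (p in c(genotype_path, pedigree_path, phenotype_path, gene_map_path))
    if (!file.exists(p))
      np_stop(paste("file not found:", p), "nestpath_io_error")

  geno <- switch(dialect,
                 tsv = read_genotypes_tsv(genotype_path),
                 plink_raw = read_genotypes_raw(genotype_path),
                 vcf = read_genotypes_vcf(genotype_path))
  ped <- read_pedigree(pedigree_path)
  phe <- read.table(phenotype_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = c(subject_id = "character"))
  gm <- read.table(gene_map_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("snp_id", "gene") %in% names(gm)))
    np_stop("gene map must have columns snp_id and gene",
            "nestpath_mapping_error")
  gene_of_snp <- setNames(as.character(gm$gene), as.character(gm$snp_id))

  if (!is.null(roles_path)) {
    roles <- jsonlite::read_json(roles_path, simplifyVector = TRUE)
    phenotypes <- as.character(roles$phenotypes %||% character())
    pheno_covariates <- as.character(roles$pheno_covariates %||% character())
    geno_covariates <- as.character(roles$geno_covariates %||% character())
  }
  if (is.null(phenotypes))
    phenotypes <- setdiff(names(phe),
                          c("subject_id", pheno_covariates, geno_covariates))

  ids <- rownames(geno)
  unknown <- setdiff(ids, ped$subject_id)
  if (length(unknown))
    np_stop(paste("genotyped subjects missing from pedigree:",
                  paste(unknown, collapse = ", ")),
            "nestpath_alignment_error")
  unknown <- setdiff(ids, phe$subject_id)
  if (length(unknown))
    np_stop(paste("genotyped subjects missing from phenotype table:",
                  paste(unknown, collapse = ", ")),
            "nestpath_alignment_error")

  dat <- merge(ped, phe, by = "subject_id", sort = FALSE)
  dat <- dat[match(ids, dat$subject_id), , drop = FALSE]
  study <- study_frame(dat, phenotypes = phenotypes,
                       pheno_covariates = pheno_covariates %||% character(),
                       geno_covariates = geno_covariates %||% character())

  gb <- genotype_block(geno, gene_of_snp)
  oriented <- orient_minor_allele(gb)
  prov <- sprintf("read_dataset(dialect=%s) from %s", dialect, genotype_path)
  if (length(oriented$flipped))
    prov <- paste0(prov, "; flipped to minor allele: ",
                   paste(oriented$flipped, collapse = ", "))
  dataset_bundle(study, oriented$block, provenance = prov)
}

# flip SNP columns coded on the major allele so codes count minor alleles
orient_minor_allele <- function(gb) {
  m <- gb$matrix
  f <- coded_allele_freq(m)
  flip <- which(!is.na(f) & f > 0.5)
  for (j in flip) m[, j] <- 2L - m[, j]
  gb$matrix <- m
  gb$minor_allele_coded <- TRUE
  list(block = gb, flipped = colnames(m)[flip])
}

read_genotypes_tsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE,
                  colClasses = c(subject_id = "character"))
  if (!"subject_id" %in% names(x))
    np_stop("genotype TSV must have a subject_id column",
            "nestpath_format_error")
  m <- as.matrix(x[, setdiff(names(x), "subject_id"), drop = FALSE])
  rownames(m) <- x$subject_id
  check_codes(m)
}

# PLINK additive recode: FID IID PAT MAT SEX PHENOTYPE SNP1_A SNP2_C ...
read_genotypes_raw <- function(path) {
  x <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE, na.strings = c("NA"))
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(x)))
    np_stop("not a PLINK .raw file (missing FID/IID/... header)",
            "nestpath_format_error")
  snps <- setdiff(names(x), meta)
  m <- as.matrix(x[, snps, drop = FALSE])
  # strip the _<counted allele> suffix plink appends to SNP names
  colnames(m) <- sub("_[ACGT0-9]+$", "", snps)
  rownames(m) <- as.character(x$IID)
  check_codes(m)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    np_stop("VCF import requires the vcfR package", "nestpath_io_error")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  fix <- vcfR::getFIX(v)
  missing_id <- is.na(ids) | ids == "."
  ids[missing_id] <- paste0(fix[missing_id, "CHROM"], "_",
                            fix[missing_id, "POS"])
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(a != "0")
  })
  m <- t(dos)
  colnames(m) <- ids
  check_codes(m)
}

check_codes <- function(m) {
  bad <- !(m %in% c(0, 1, 2) | is.na(m))
  if (any(bad))
    np_stop("genotype codes outside {0,1,2,NA}", "nestpath_format_error")
  storage.mode(m) <- "integer"
  m
}

# two-column TSV (subject_id, sibship_id) or headerless PLINK .fam;
# .fam parent links are collapsed: the sibship is the family id
read_pedigree <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("subject_id", first, fixed = TRUE)) {
    ped <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE,
                      colClasses = "character")
    if (!all(c("subject_id", "sibship_id") %in% names(ped)))
      np_stop("pedigree TSV needs subject_id and sibship_id columns",
              "nestpath_format_error")
    ped[, c("subject_id", "sibship_id")]
  } else {
    fam <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (ncol(fam) < 2)
      np_stop("pedigree file needs at least FID and IID columns",
              "nestpath_format_error")
    data.frame(subject_id = fam[[2]], sibship_id = fam[[1]],
               stringsAsFactors = FALSE)
  }
}

#' Write a dataset bundle to TSV files
#'
#' Writes `<prefix>.geno.tsv`, `<prefix>.ped.tsv`, `<prefix>.pheno.tsv`,
#' `<prefix>.genemap.tsv` and `<prefix>.roles.json` such that
#' `read_dataset()` on the written files reproduces the bundle exactly
#' (numeric columns are written at full precision; missing values as `NA`).
#'
#' @param bundle a [dataset_bundle()].
#' @param out_prefix output path prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(bundle, out_prefix) {
  stopifnot(inherits(bundle, "dataset_bundle"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir))
    np_stop(paste("output directory does not exist:", dir),
            "nestpath_io_error")
  paths <- c(geno = paste0(out_prefix, ".geno.tsv"),
             ped = paste0(out_prefix, ".ped.tsv"),
             pheno = paste0(out_prefix, ".pheno.tsv"),
             genemap = paste0(out_prefix, ".genemap.tsv"),
             roles = paste0(out_prefix, ".roles.json"))

  g <- data.frame(subject_id = rownames(bundle$genotypes$matrix),
                  bundle$genotypes$matrix, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write_tsv(g, paths["geno"])

  ped <- bundle$study$data[, c("subject_id", "sibship_id")]
  write_tsv(ped, paths["ped"])

  phe_cols <- c("subject_id",
                setdiff(names(bundle$study$data),
                        c("subject_id", "sibship_id")))
  write_tsv(bundle$study$data[, phe_cols, drop = FALSE], paths["pheno"])

  gm <- data.frame(snp_id = names(bundle$genotypes$gene_of_snp),
                   gene = unname(bundle$genotypes$gene_of_snp),
                   stringsAsFactors = FALSE)
  write_tsv(gm, paths["genemap"])

  jsonlite::write_json(
    list(phenotypes = bundle$study$phenotypes,
         pheno_covariates = bundle$study$pheno_covariates,
         geno_covariates = bundle$study$geno_covariates),
    paths["roles"])
  invisible(paths)
}

write_tsv <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]]))
      df[[j]] <- vapply(df[[j]], function(v)
        if (is.na(v)) "NA" else format(v, digits = 17), character(1))
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) np_stop(paste("cannot write", path), "nestpath_io_error")
}
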