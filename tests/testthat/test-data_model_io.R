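# --- reading, orientation, validation --------------------------------------

write_toy_inputs <- function(dir, geno, ped, phe, gm) {
  paths <- list(geno = file.path(dir, "g.tsv"), ped = file.path(dir, "p.tsv"),
                phe = file.path(dir, "y.tsv"), gm = file.path(dir, "m.tsv"))
  writeLines(geno, paths$geno); writeLines(ped, paths$ped)
  writeLines(phe, paths$phe); writeLines(gm, paths$gm)
  paths
}

test_that("a minimal TSV dataset reads into an aligned bundle", {
  dir <- tempfile(); dir.create(dir)
  p <- write_toy_inputs(dir,
    geno = c("subject_id\tsnpA\tsnpB", "a\t0\t1", "b\t1\t0", "c\t0\t2"),
    ped = c("subject_id\tsibship_id", "a\tf1", "b\tf1", "c\tf2"),
    phe = c("subject_id\ty", "a\t1.5", "b\t-0.5", "c\t0"),
    gm = c("snp_id\tgene", "snpA\tg1", "snpB\tg1"))
  b <- read_dataset(p$geno, p$ped, p$phe, p$gm, dialect = "tsv")
  expect_s3_class(b, "dataset_bundle")
  expect_equal(nrow(b$genotypes$matrix), 3)
  expect_equal(ncol(b$genotypes$matrix), 2)
  expect_equal(length(unique(b$genotypes$gene_of_snp)), 1)
  expect_equal(b$study$data$sibship_id, c("f1", "f1", "f2"))
})

test_that("SNPs coded on the major allele are flipped to minor at read", {
  dir <- tempfile(); dir.create(dir)
  # snpA coded-allele frequency 8/10 = 0.8 -> must be flipped to 0.2
  p <- write_toy_inputs(dir,
    geno = c("subject_id\tsnpA\tsnpB",
             "a\t2\t1", "b\t2\t0", "c\t2\t0", "d\t1\t0", "e\t1\t1"),
    ped = c("subject_id\tsibship_id", "a\tf1", "b\tf2", "c\tf3", "d\tf4",
            "e\tf5"),
    phe = c("subject_id\ty", "a\t1", "b\t0", "c\t1", "d\t0", "e\t1"),
    gm = c("snp_id\tgene", "snpA\tg1", "snpB\tg1"))
  b <- read_dataset(p$geno, p$ped, p$phe, p$gm)
  f <- colSums(b$genotypes$matrix) / (2 * nrow(b$genotypes$matrix))
  expect_equal(unname(f[["snpA"]]), 0.2)
  expect_true(all(f <= 0.5 + 1e-12))
  expect_match(b$provenance, "flipped.*snpA")
  expect_equal(unname(b$genotypes$matrix[, "snpA"]), c(0L, 0L, 0L, 1L, 1L))
})

test_that("structural errors are raised as classed conditions", {
  dir <- tempfile(); dir.create(dir)
  p <- write_toy_inputs(dir,
    geno = c("subject_id\tsnpA\tsnpB", "a\t0\t1", "b\t1\t0"),
    ped = c("subject_id\tsibship_id", "a\tf1", "b\tf1"),
    phe = c("subject_id\ty", "a\t1", "b\t0"),
    gm = c("snp_id\tgene", "snpA\tg1"))            # snpB unmapped
  expect_error(read_dataset(p$geno, p$ped, p$phe, p$gm),
               class = "nestpath_mapping_error")

  p2 <- write_toy_inputs(dir,
    geno = c("subject_id\tsnpA", "a\t0", "zz\t1"),  # zz not in pedigree
    ped = c("subject_id\tsibship_id", "a\tf1", "b\tf1"),
    phe = c("subject_id\ty", "a\t1", "b\t0"),
    gm = c("snp_id\tgene", "snpA\tg1"))
  expect_error(read_dataset(p2$geno, p2$ped, p2$phe, p2$gm),
               class = "nestpath_alignment_error")

  p3 <- write_toy_inputs(dir,
    geno = c("subject_id\tsnpA", "a\t3", "b\t1"),   # code 3 invalid
    ped = c("subject_id\tsibship_id", "a\tf1", "b\tf1"),
    phe = c("subject_id\ty", "a\t1", "b\t0"),
    gm = c("snp_id\tgene", "snpA\tg1"))
  expect_error(read_dataset(p3$geno, p3$ped, p3$phe, p3$gm),
               class = "nestpath_format_error")
})

test_that("PLINK .raw genotypes and .fam sibships are read and collapsed", {
  dir <- tempfile(); dir.create(dir)
  raw <- c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_T",
           "f1 a 0 0 1 -9 0 1",
           "f1 b 0 0 2 -9 1 NA",
           "f2 c 0 0 1 -9 0 2")
  fam <- c("f1 a 0 0 1 -9", "f1 b 0 0 2 -9", "f2 c 0 0 1 -9")
  writeLines(raw, file.path(dir, "d.raw"))
  writeLines(fam, file.path(dir, "d.fam"))
  writeLines(c("subject_id\ty", "a\t1", "b\t0", "c\t1"),
             file.path(dir, "y.tsv"))
  writeLines(c("snp_id\tgene", "rs1\tg1", "rs2\tg1"),
             file.path(dir, "m.tsv"))
  b <- read_dataset(file.path(dir, "d.raw"), file.path(dir, "d.fam"),
                    file.path(dir, "y.tsv"), file.path(dir, "m.tsv"),
                    dialect = "plink_raw")
  expect_equal(colnames(b$genotypes$matrix), c("rs1", "rs2"))
  expect_equal(b$study$data$sibship_id, c("f1", "f1", "f2"))
  expect_true(is.na(b$genotypes$matrix["b", "rs2"]))
})

test_that("minimal VCF import converts GT to minor-allele dosage", {
  dir <- tempfile(); dir.create(dir)
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb\tc",
           "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
           "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0/0")
  writeLines(vcf, file.path(dir, "d.vcf"))
  writeLines(c("subject_id\tsibship_id", "a\tf1", "b\tf1", "c\tf2"),
             file.path(dir, "p.tsv"))
  writeLines(c("subject_id\ty", "a\t1", "b\t0", "c\t1"),
             file.path(dir, "y.tsv"))
  writeLines(c("snp_id\tgene", "rs1\tg1", "rs2\tg1"), file.path(dir, "m.tsv"))
  b <- read_dataset(file.path(dir, "d.vcf"), file.path(dir, "p.tsv"),
                    file.path(dir, "y.tsv"), file.path(dir, "m.tsv"),
                    dialect = "vcf")
  expect_equal(unname(b$genotypes$matrix[, "rs1"]), c(0L, 1L, 2L))
  expect_true(is.na(b$genotypes$matrix["b", "rs2"]))
  expect_equal(unname(b$genotypes$matrix["a", "rs2"]), 1L)
})

# --- monomorphic filter -----------------------------------------------------

test_that("monomorphic SNPs are removed, polymorphic retained, idempotently", {
  set.seed(41)
  n <- 12
  m <- sapply(runif(10, 0.2, 0.4), function(f) rbinom(n, 2, f))
  m[, c(2, 5, 9)] <- 0L                   # exactly three constant columns
  m[, 1] <- c(0L, 1L, rep(0L, n - 2))     # {0,1,0...} must be retained
  while (any(apply(m[, -c(2, 5, 9)], 2, function(v) length(unique(v)) == 1)))
    m[, -c(2, 5, 9)] <- sapply(runif(7, 0.2, 0.4), function(f) rbinom(n, 2, f))
  colnames(m) <- paste0("s", 1:10)
  b <- make_bundle(m, rep(paste0("f", 1:6), each = 2),
                   setNames(rep(c("g1", "g2"), each = 5), paste0("s", 1:10)))
  res <- filter_monomorphic(b)
  expect_setequal(res$removed_snp_ids, c("s2", "s5", "s9"))
  expect_true("s1" %in% colnames(res$bundle$genotypes$matrix))
  # idempotence
  res2 <- filter_monomorphic(res$bundle)
  expect_length(res2$removed_snp_ids, 0)
  expect_equal(res2$bundle$genotypes$matrix, res$bundle$genotypes$matrix)
  # genes left without SNPs are dropped from the map
  m2 <- m; m2[, 1:5] <- 0L
  b2 <- make_bundle(m2, rep(paste0("f", 1:6), each = 2),
                    setNames(rep(c("g1", "g2"), each = 5), paste0("s", 1:10)))
  res3 <- filter_monomorphic(b2)
  expect_false("g1" %in% unique(res3$bundle$genotypes$gene_of_snp))
})

test_that("an all-monomorphic pathway is an error", {
  m <- matrix(0L, 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b")))
  b <- make_bundle(m, c("f1", "f1", "f2", "f2"), c(a = "g1", b = "g1"))
  expect_error(filter_monomorphic(b), class = "nestpath_empty_pathway_error")
})

# --- round trip -------------------------------------------------------------

test_that("write_dataset/read_dataset round-trips bundles exactly", {
  for (seed in 1:5) {
    b <- random_bundle(seed)
    dir <- tempfile(); dir.create(dir)
    prefix <- file.path(dir, "rt")
    paths <- write_dataset(b, prefix)
    b2 <- read_dataset(paths[["geno"]], paths[["ped"]], paths[["pheno"]],
                       paths[["genemap"]], dialect = "tsv",
                       roles_path = paths[["roles"]])
    expect_identical(b2$genotypes$matrix, b$genotypes$matrix)
    expect_identical(b2$genotypes$gene_of_snp, b$genotypes$gene_of_snp)
    expect_identical(b2$study$data$sibship_id, b$study$data$sibship_id)
    expect_equal(b2$study$data$y, b$study$data$y)
    expect_equal(b2$study$data$age, b$study$data$age)
    expect_identical(b2$study$phenotypes, b$study$phenotypes)
    expect_identical(b2$study$pheno_covariates, b$study$pheno_covariates)
  }
})

test_that("round trip preserves missing genotypes and a 6-sib family", {
  m <- matrix(c(0L, 1L, 2L, NA, 1L, 0L,
                1L, NA, 0L, 1L, 2L, 1L), nrow = 6,
              dimnames = list(sprintf("s%d", 1:6), c("a", "b")))
  b <- make_bundle(m, rep("bigfam", 6), c(a = "g1", b = "g1"))
  dir <- tempfile(); dir.create(dir)
  paths <- write_dataset(b, file.path(dir, "rt"))
  b2 <- read_dataset(paths[["geno"]], paths[["ped"]], paths[["pheno"]],
                     paths[["genemap"]], roles_path = paths[["roles"]])
  expect_identical(b2$genotypes$matrix, b$genotypes$matrix)
  expect_equal(b2$study$data$sibship_id, rep("bigfam", 6))
})

test_that("after orientation every SNP has coded frequency at most 0.5", {
  for (seed in 6:10) {
    b <- random_bundle(seed)
    dir <- tempfile(); dir.create(dir)
    paths <- write_dataset(b, file.path(dir, "o"))
    b2 <- read_dataset(paths[["geno"]], paths[["ped"]], paths[["pheno"]],
                       paths[["genemap"]], roles_path = paths[["roles"]])
    f <- colSums(b2$genotypes$matrix, na.rm = TRUE) /
      (2 * colSums(!is.na(b2$genotypes$matrix)))
    expect_true(all(f <= 0.5 + 1e-12))
  }
})
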