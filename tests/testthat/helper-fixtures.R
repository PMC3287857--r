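# fixtures are built in code; nothing is stored on disk

# generic builder: genotype matrix + sibship assignment -> bundle
make_bundle <- function(m, sibship_id, gene_of_snp,
                        age = NULL, smoking = NULL, y = NULL,
                        geno_covariates = character()) {
  n <- nrow(m)
  ids <- rownames(m) %||% sprintf("s%03d", seq_len(n))
  rownames(m) <- ids
  dat <- data.frame(subject_id = ids, sibship_id = sibship_id,
                    age = age %||% seq(30, 60, length.out = n),
                    smoking = smoking %||% rep_len(c(0, 1), n),
                    y = y %||% seq_len(n) / n,
                    stringsAsFactors = FALSE)
  st <- study_frame(dat, phenotypes = "y",
                    pheno_covariates = c("age", "smoking"),
                    geno_covariates = geno_covariates)
  gb <- genotype_block(m, gene_of_snp, minor_allele_coded = TRUE)
  dataset_bundle(st, gb, "test fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the tiny nested fixture: 2 sibships x 2 subjects x 2 genes x 2 SNPs
tiny_bundle <- function() {
  m <- matrix(c(0, 1, 2, 1,
                1, 0, 1, 2,
                0, 0, 1, 1,
                2, 1, 0, 1), nrow = 4,
              dimnames = list(paste0("s", 1:4),
                              c("g1_a", "g1_b", "g2_a", "g2_b")))
  make_bundle(m, c("f1", "f1", "f2", "f2"),
              c(g1_a = "g1", g1_b = "g1", g2_a = "g2", g2_b = "g2"))
}

# random small bundle for property tests (always polymorphic columns)
random_bundle <- function(seed, n = 30, G = 2, S_g = 3,
                          missing_rate = 0.05) {
  set.seed(seed)
  S <- G * S_g
  maf <- runif(S, 0.05, 0.45)
  repeat {
    m <- sapply(maf, function(f) rbinom(n, 2, f))
    if (all(apply(m, 2, function(v) length(unique(v)) > 1))) break
  }
  if (missing_rate > 0) {
    drop <- runif(n * S) < missing_rate
    # keep every column polymorphic after masking
    m2 <- m; m2[drop] <- NA
    ok <- apply(m2, 2, function(v) length(unique(v[!is.na(v)])) > 1)
    m[drop & rep(ok, each = n)] <- NA
  }
  genes <- paste0("g", rep(seq_len(G), each = S_g))
  snps <- paste0(genes, "_s", rep(seq_len(S_g), G))
  colnames(m) <- snps
  rownames(m) <- sprintf("s%03d", seq_len(n))
  sib <- sprintf("f%03d", rep(seq_len(ceiling(n / 2)), each = 2)[seq_len(n)])
  make_bundle(m, sib, setNames(genes, snps))
}

# write a bundle's inputs as the separate TSV files read_dataset() expects
write_input_files <- function(bundle, dir = tempfile("np")) {
  dir.create(dir)
  paths <- write_dataset(bundle, file.path(dir, "data"))
  as.list(paths)
}

# exchangeable-cluster marginal log-likelihood for the LMM grid oracle
lmm_marginal_loglik <- function(y, X, beta, cluster, s2u, s2e) {
  r <- y - as.numeric(X %*% beta)
  ll <- 0
  for (ii in split(seq_along(y), cluster)) {
    ni <- length(ii)
    V <- matrix(s2u, ni, ni) + diag(s2e, ni)
    ll <- ll - 0.5 * (ni * log(2 * pi) +
                        as.numeric(determinant(V, TRUE)$modulus) +
                        as.numeric(r[ii] %*% solve(V, r[ii])))
  }
  ll
}

gls_beta <- function(y, X, cluster, s2u, s2e) {
  A <- matrix(0, ncol(X), ncol(X)); b <- numeric(ncol(X))
  for (ii in split(seq_along(y), cluster)) {
    ni <- length(ii)
    V <- matrix(s2u, ni, ni) + diag(s2e, ni)
    Vi <- solve(V)
    Xi <- X[ii, , drop = FALSE]
    A <- A + t(Xi) %*% Vi %*% Xi
    b <- b + t(Xi) %*% Vi %*% y[ii]
  }
  solve(A, b)
}
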