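#' Specification of the genotype (gene) model
#'
#' Options for the stage-1 binomial logistic mixed model. Genotypes
#' `w ~ Binomial(2, pi)` are modelled on the logit scale as a fixed part
#' (per-SNP intercepts by default, capturing heterogeneous minor allele
#' frequencies under Hardy-Weinberg equilibrium, plus optional subject-level
#' covariates) and nested normal random effects: sibship, subject, and
#' gene-within-subject.
#'
#' @param include_sibship_effect logical; omit for unrelated (all-singleton)
#'   data. Default `NULL` chooses `TRUE` when any sibship has more than one
#'   member.
#' @param genotype_covariates character vector of covariate column names
#'   entering the genotype model (e.g. `"smoking"`).
#' @param intercept_mode `"per_snp"` (default), `"per_gene"` or `"shared"`.
#' @param max_iter outer iteration cap for the variance-component optimizer.
#' @param reltol relative convergence tolerance on the Laplace log-likelihood.
#' @param fixed_variance optional named numeric `c(sib=,subj=,gene=)` of
#'   variance components to hold fixed (no estimation); components for
#'   excluded effects are ignored. Mainly for testing sub-problems.
#' @return An object of class `gene_model_spec`.
#' @export
gene_model_spec <- function(include_sibship_effect = NULL,
                            genotype_covariates = character(),
                            intercept_mode = c("per_snp", "per_gene",
                                               "shared"),
                            max_iter = 500, reltol = 1e-8,
                            fixed_variance = NULL) {
  intercept_mode <- match.arg(intercept_mode)
  stopifnot(reltol > 0, max_iter >= 1)
  structure(list(include_sibship_effect = include_sibship_effect,
                 genotype_covariates = genotype_covariates,
                 intercept_mode = intercept_mode,
                 max_iter = max_iter, reltol = reltol,
                 fixed_variance = fixed_variance),
            class = "gene_model_spec")
}

# ---- model frame -----------------------------------------------------------

# Long format over non-missing genotype cells plus sparse designs.
# Missing cells are simply absent (cell-wise deletion inside the likelihood).
build_gene_model_data <- function(bundle, spec) {
  study <- bundle$study
  gb <- bundle$genotypes
  m <- gb$matrix
  N <- nrow(m); S <- ncol(m)
  genes <- genes_of(gb)
  G <- length(genes)
  gidx_of_snp <- match(unname(gb$gene_of_snp), genes)

  sib_levels <- unique(study$data$sibship_id)
  sib_of_subj <- match(study$data$sibship_id, sib_levels)
  include_sib <- spec$include_sibship_effect
  if (is.null(include_sib)) include_sib <- any(table(sib_of_subj) > 1)

  keep <- which(!is.na(m))                  # column-major cell index
  subj <- ((keep - 1L) %% N) + 1L
  snp <- ((keep - 1L) %/% N) + 1L
  w <- as.integer(m[keep])
  gene <- gidx_of_snp[snp]
  ncell <- length(keep)

  # fixed design: intercept structure + genotype covariates
  Xint <- switch(spec$intercept_mode,
    per_snp = Matrix::sparseMatrix(i = seq_len(ncell), j = snp, x = 1,
                                   dims = c(ncell, S),
                                   dimnames = list(NULL, colnames(m))),
    per_gene = Matrix::sparseMatrix(i = seq_len(ncell), j = gene, x = 1,
                                    dims = c(ncell, G),
                                    dimnames = list(NULL, paste0("(Intercept|",
                                                                 genes, ")"))),
    shared = Matrix::Matrix(1, ncell, 1, sparse = TRUE,
                            dimnames = list(NULL, "(Intercept)")))
  covs <- spec$genotype_covariates
  if (length(covs)) {
    cm <- as.matrix(study$data[, covs, drop = FALSE])
    if (!is.numeric(cm))
      np_stop("genotype covariates must be numeric", "nestpath_design_error")
    Xc <- Matrix::Matrix(cm[subj, , drop = FALSE], sparse = TRUE)
    colnames(Xc) <- covs
    X <- cbind(Xint, Xc)
  } else X <- Xint
  p <- ncol(X)
  if (Matrix::rankMatrix(as.matrix(Matrix::crossprod(X)))[1] < p)
    np_stop("fixed-effects design is rank deficient",
            "nestpath_design_error")

  blocks <- list()
  if (include_sib)
    blocks$sib <- Matrix::sparseMatrix(i = seq_len(ncell),
                                       j = sib_of_subj[subj], x = 1,
                                       dims = c(ncell, length(sib_levels)))
  blocks$subj <- Matrix::sparseMatrix(i = seq_len(ncell), j = subj, x = 1,
                                      dims = c(ncell, N))
  blocks$gene <- Matrix::sparseMatrix(i = seq_len(ncell),
                                      j = (subj - 1L) * G + gene, x = 1,
                                      dims = c(ncell, N * G))
  Z <- do.call(cbind, blocks)
  block_sizes <- vapply(blocks, ncol, integer(1))

  cov_values <- if (length(covs))
    as.matrix(study$data[, covs, drop = FALSE]) else
      matrix(0, N, 0)

  list(w = w, X = X, Z = Z, block_sizes = block_sizes,
       include_sib = include_sib, N = N, S = S, G = G,
       genes = genes, snp_ids = colnames(m),
       gidx_of_snp = gidx_of_snp, cov_values = cov_values,
       subj_ids = study$data$subject_id, sib_levels = sib_levels,
       sib_of_subj = sib_of_subj, subj = subj, snp = snp, gene = gene,
       fixed_names = colnames(X))
}

binom_loglik <- function(w, eta) {
  sum(dbinom(w, 2, plogis(eta), log = TRUE))
}

# ---- penalized IRLS for the joint conditional mode of (beta, u) ------------

# Spherical parameterization b = sigma * u, u ~ N(0, I): the penalized
# objective  loglik(eta) - ||u||^2 / 2  with eta = X beta + Z Lambda u is
# maximized by Newton steps on the joint system; stays well defined at
# sigma = 0 (the corresponding columns vanish and u shrinks to 0).
pirls <- function(dat, sigma, beta, u, tol = 1e-10, max_iter = 60,
                  fixed_beta = FALSE) {
  lam <- rep(sigma, dat$block_sizes)
  ZL <- dat$Z %*% Matrix::Diagonal(x = lam)
  A <- if (fixed_beta) ZL else cbind(dat$X, ZL)
  p <- if (fixed_beta) 0L else ncol(dat$X)
  q <- ncol(dat$Z)
  pen_diag <- c(rep(0, p), rep(1, q))
  offset <- if (fixed_beta) as.numeric(dat$X %*% beta) else 0
  x <- c(if (!fixed_beta) beta, u)

  eta <- offset + as.numeric(A %*% x)
  pen <- binom_loglik(dat$w, eta) - 0.5 * sum(u^2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- 2 * plogis(eta)
    wts <- pmax(mu * (1 - mu / 2), 1e-10)       # 2 pi (1 - pi)
    r <- dat$w - mu
    H <- Matrix::forceSymmetric(
      Matrix::crossprod(A, A * wts) + Matrix::Diagonal(x = pen_diag))
    rhs <- Matrix::crossprod(A, wts * (eta - offset) + r)
    x_new <- as.numeric(Matrix::solve(H, rhs))
    # step-halving to guarantee ascent of the penalized log-likelihood
    step <- 1
    repeat {
      x_try <- x + step * (x_new - x)
      u_try <- x_try[(p + 1):(p + q)]
      eta_try <- offset + as.numeric(A %*% x_try)
      pen_try <- binom_loglik(dat$w, eta_try) - 0.5 * sum(u_try^2)
      if (pen_try >= pen - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    delta <- abs(pen_try - pen)
    x <- x_try; eta <- eta_try; pen <- pen_try
    if (delta < tol * (abs(pen) + 1)) { converged <- TRUE; break }
  }
  u <- x[(p + 1):(p + q)]
  mu <- 2 * plogis(eta)
  wts <- pmax(mu * (1 - mu / 2), 1e-10)
  Mbb <- Matrix::forceSymmetric(
    Matrix::crossprod(ZL, ZL * wts) + Matrix::Diagonal(q))
  logdet <- as.numeric(Matrix::determinant(Mbb, logarithm = TRUE)$modulus)
  list(beta = if (fixed_beta) beta else x[seq_len(p)], u = u, eta = eta,
       loglik = binom_loglik(dat$w, eta), pen = pen, logdet = logdet,
       laplace = pen - 0.5 * logdet, converged = converged, iter = it)
}

# deterministic start: empirical-logit values for the intercept indicator
# columns, zero slopes for covariates
glm_init_beta <- function(dat) {
  beta <- rep(0, ncol(dat$X))
  for (j in seq_len(ncol(dat$X))) {
    col <- dat$X[, j]
    idx <- which(col != 0)
    if (length(idx) && all(abs(col[idx] - 1) < 1e-12)) {
      f <- (sum(dat$w[idx]) + 0.5) / (2 * length(idx) + 1)
      beta[j] <- qlogis(f)
    }
  }
  beta
}

# ---- main fit --------------------------------------------------------------

#' Fit the nested random-effects binomial genotype model
#'
#' Maximizes the Laplace-approximate marginal likelihood of the stage-1
#' model: given the random effects, each genotype is Binomial(2, pi) with
#' `logit(pi) = fixed part + b_sibship + b_subject + b_gene(subject)`, the
#' random effects being independent mean-zero normals with variances
#' `sigma2_sib`, `sigma2_subj`, `sigma2_gene`. Conditional modes of
#' `(beta, b)` are found by penalized iteratively reweighted least squares on
#' the sparse joint system; the profiled Laplace objective is optimized over
#' the random-effect standard deviations with the boundary at zero handled
#' exactly (a component may be estimated as 0). The fit is deterministic:
#' random effects start at zero and fixed effects at empirical-logit values.
#'
#' Missing genotype cells are dropped from the likelihood (the subject is
#' retained; its remaining cells still inform its random effects).
#'
#' @param bundle a [dataset_bundle()], already filtered of monomorphic SNPs
#'   (see [filter_monomorphic()]).
#' @param spec a [gene_model_spec()].
#' @return An object of class `gene_model_fit` with components
#'   `fixed_effects`, `variance_components` (named `sib`, `subj`, `gene`),
#'   `eb_matrix` (subjects x genes empirical Bayes estimates),
#'   `log_likelihood` (Laplace), `converged`, `n_iterations`.
#' @export
fit_gene_model <- function(bundle, spec = gene_model_spec()) {
  stopifnot(inherits(bundle, "dataset_bundle"),
            inherits(spec, "gene_model_spec"))
  dat <- build_gene_model_data(bundle, spec)
  comp_names <- names(dat$block_sizes)      # subset of c("sib","subj","gene")

  beta0 <- glm_init_beta(dat)
  u0 <- rep(0, ncol(dat$Z))
  env <- new.env()
  env$beta <- beta0; env$u <- u0; env$n_obj <- 0L

  objective <- function(sigma) {
    sigma <- abs(sigma)
    fit <- pirls(dat, sigma, env$beta, env$u)
    env$beta <- fit$beta; env$u <- fit$u     # warm start
    env$n_obj <- env$n_obj + 1L
    -fit$laplace
  }

  if (!is.null(spec$fixed_variance)) {
    fv <- spec$fixed_variance
    sigma <- sqrt(pmax(fv[comp_names], 0))
    sigma[is.na(sigma)] <- 0
    opt_conv <- TRUE
  } else {
    k <- length(comp_names)
    start <- rep(0.5, k)
    if (k == 1) {
      opt <- optim(start, objective, method = "Brent", lower = 0, upper = 5,
                   control = list(maxit = spec$max_iter))
    } else {
      opt <- optim(start, objective, method = "Nelder-Mead",
                   control = list(reltol = spec$reltol,
                                  maxit = spec$max_iter * 10))
    }
    sigma <- abs(opt$par)
    sigma[sigma < 1e-5] <- 0                # boundary snap
    opt_conv <- opt$convergence == 0
  }
  names(sigma) <- comp_names

  final <- pirls(dat, sigma, env$beta, env$u)
  if (!final$converged && !opt_conv)
    np_warn("gene model: inner PIRLS did not fully converge",
            "nestpath_convergence_warning")

  sg <- unname(sigma["gene"])
  u_gene <- final$u[(ncol(dat$Z) - dat$N * dat$G + 1):ncol(dat$Z)]
  eb <- matrix(sg * u_gene, nrow = dat$N, ncol = dat$G, byrow = TRUE,
               dimnames = list(dat$subj_ids, dat$genes))

  vc <- c(sib = 0, subj = 0, gene = 0)
  vc[comp_names] <- sigma^2

  u_by_block <- split(final$u, rep(factor(comp_names, levels = comp_names),
                                   dat$block_sizes))
  b_sib <- if (dat$include_sib)
    setNames(sigma["sib"] * u_by_block$sib, dat$sib_levels) else
      setNames(rep(0, length(dat$sib_levels)), dat$sib_levels)
  b_subj <- setNames(unname(sigma["subj"] * u_by_block$subj), dat$subj_ids)

  structure(list(fixed_effects = setNames(final$beta, dat$fixed_names),
                 variance_components = vc,
                 eb_matrix = eb,
                 log_likelihood = final$laplace,
                 converged = final$converged && opt_conv,
                 n_iterations = env$n_obj,
                 b_sibship = b_sib, b_subject = b_subj,
                 spec = spec, data = dat),
            class = "gene_model_fit")
}

#' @exportS3Method base::print
print.gene_model_fit <- function(x, ...) {
  cat(sprintf("gene_model_fit: %d subjects, %d SNPs in %d genes\n",
              x$data$N, x$data$S, x$data$G))
  cat(sprintf("  Laplace log-likelihood: %.4f (%s)\n", x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  cat("  variance components:",
      paste(sprintf("%s=%.4f", names(x$variance_components),
                    x$variance_components), collapse = ", "), "\n")
  invisible(x)
}

#' Empirical Bayes gene-burden estimates
#'
#' Returns the subjects x genes matrix of empirical Bayes estimates: the
#' conditional (posterior) modes of the gene-within-subject random effects at
#' the fitted parameters (mode = mean under the Laplace Gaussian
#' approximation). A subject carrying more minor alleles in a gene has a
#' strictly larger estimate for that gene, all else equal; with
#' `sigma2_gene = 0` all entries are exactly zero.
#'
#' @param fit a converged [fit_gene_model()] result.
#' @param newdata optional [dataset_bundle()] with the same SNPs and
#'   subjects: conditional modes are recomputed for its genotypes at the
#'   *fitted* parameters (fixed effects and variance components held fixed).
#' @return numeric matrix, subjects x genes.
#' @export
empirical_bayes_estimates <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "gene_model_fit"))
  if (!fit$converged)
    np_stop("gene model fit did not converge; refusing EB extraction",
            "nestpath_convergence_error")
  if (is.null(newdata)) return(fit$eb_matrix)
  dat <- build_gene_model_data(newdata, fit$spec)
  if (!identical(dat$fixed_names, fit$data$fixed_names))
    np_stop("newdata design does not match the fitted model",
            "nestpath_design_error")
  sigma <- sqrt(fit$variance_components[names(dat$block_sizes)])
  res <- pirls(dat, sigma, unname(fit$fixed_effects),
               rep(0, ncol(dat$Z)), fixed_beta = TRUE)
  sg <- sqrt(fit$variance_components[["gene"]])
  u_gene <- res$u[(ncol(dat$Z) - dat$N * dat$G + 1):ncol(dat$Z)]
  matrix(sg * u_gene, nrow = dat$N, ncol = dat$G, byrow = TRUE,
         dimnames = list(dat$subj_ids, dat$genes))
}

#' Fitted genotype probability for one subject and SNP
#'
#' Plug-in success probability `pi_hat` of the Binomial(2, pi) genotype
#' model, evaluated at the fitted fixed effects and the conditional modes of
#' the subject's random effects.
#'
#' @param fit a [fit_gene_model()] result.
#' @param subject subject id (string).
#' @param snp SNP id (string).
#' @return probability in (0, 1).
#' @export
predict_genotype_probability <- function(fit, subject, snp) {
  dat <- fit$data
  jj <- match(subject, dat$subj_ids)
  ss <- match(snp, dat$snp_ids)
  if (is.na(jj) || is.na(ss))
    np_stop("unknown subject or SNP", "nestpath_lookup_error")
  gsnp <- dat$gidx_of_snp[ss]
  beta <- fit$fixed_effects
  eta <- switch(fit$spec$intercept_mode,
                per_snp = beta[[dat$snp_ids[ss]]],
                per_gene = beta[[paste0("(Intercept|", dat$genes[gsnp], ")")]],
                shared = beta[["(Intercept)"]])
  for (cv in fit$spec$genotype_covariates)
    eta <- eta + beta[[cv]] * dat$cov_values[jj, cv]
  eta <- eta + fit$b_sibship[[dat$sib_levels[dat$sib_of_subj[jj]]]] +
    fit$b_subject[[subject]] + fit$eb_matrix[jj, gsnp]
  unname(plogis(eta))
}
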