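#' Specification of the stage-2 phenotype model
#'
#' Describes which trait is analyzed, which covariates enter, which genes'
#' empirical Bayes columns receive pathway coefficients `gamma_1..gamma_G`,
#' and which gene-by-environment interaction terms are added.
#'
#' @param trait_name phenotype column name.
#' @param trait_type `"quantitative"` (linear mixed model with a sibship
#'   random effect) or `"binary"` (logistic GEE with exchangeable working
#'   correlation). `NULL` auto-detects from the data.
#' @param covariate_names covariates for the phenotype model (e.g. Age,
#'   Smoking).
#' @param gene_terms gene labels whose EB columns enter; `NULL` means all
#'   genes of the EB matrix.
#' @param interaction_terms list of `c(gene, covariate)` pairs.
#' @param reml logical; use REML instead of ML for the linear mixed model.
#' @return An object of class `phenotype_model_spec`.
#' @export
phenotype_model_spec <- function(trait_name, trait_type = NULL,
                                 covariate_names = character(),
                                 gene_terms = NULL,
                                 interaction_terms = list(),
                                 reml = FALSE) {
  if (length(interaction_terms) && !is.list(interaction_terms))
    interaction_terms <- list(interaction_terms)
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 covariate_names = covariate_names, gene_terms = gene_terms,
                 interaction_terms = interaction_terms, reml = reml),
            class = "phenotype_model_spec")
}

#' Assemble the stage-2 design matrix
#'
#' Builds intercept, covariate, EB gene columns, and EB-by-covariate
#' interaction columns (elementwise products), together with a term map that
#' addresses each pathway coefficient by gene label.
#'
#' @param study a [study_frame()].
#' @param eb subjects x genes EB matrix (rownames = subject ids), as from
#'   [empirical_bayes_estimates()].
#' @param spec a [phenotype_model_spec()].
#' @return list with `X` (design matrix), `y` (trait), `cluster` (sibship
#'   factor), `term_map` (`intercept`, `covariates`, `genes`, `interactions`
#'   -> column names), `complete` (logical row filter used).
#' @export
build_design <- function(study, eb, spec) {
  stopifnot(inherits(study, "study_frame"))
  ids <- study$data$subject_id
  if (is.null(rownames(eb)) || !all(ids %in% rownames(eb)))
    np_stop("EB matrix rows do not cover the study subjects",
            "nestpath_alignment_error")
  eb <- eb[ids, , drop = FALSE]
  genes <- spec$gene_terms %||% colnames(eb)
  if (!all(genes %in% colnames(eb)))
    np_stop("gene_terms not present in the EB matrix",
            "nestpath_design_error")
  for (it in spec$interaction_terms)
    if (!(it[1] %in% genes))
      np_stop("interaction gene must be among gene_terms",
              "nestpath_design_error")

  n <- length(ids)
  cols <- list(`(Intercept)` = rep(1, n))
  for (cv in spec$covariate_names) {
    v <- study$data[[cv]]
    if (is.null(v)) np_stop(paste("unknown covariate", cv),
                            "nestpath_design_error")
    cols[[cv]] <- as.numeric(v)
  }
  gene_cols <- paste0("eb_", genes)
  for (k in seq_along(genes)) cols[[gene_cols[k]]] <- eb[, genes[k]]
  int_cols <- character(0)
  for (it in spec$interaction_terms) {
    nm <- paste0("eb_", it[1], ":", it[2])
    cols[[nm]] <- eb[, it[1]] * as.numeric(study$data[[it[2]]])
    int_cols <- c(int_cols, nm)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  y <- as.numeric(study$data[[spec$trait_name]])
  if (is.null(study$data[[spec$trait_name]]))
    np_stop(paste("unknown trait", spec$trait_name),
            "nestpath_design_error")
  complete <- complete.cases(X) & !is.na(y)
  term_map <- list(intercept = "(Intercept)",
                   covariates = setNames(spec$covariate_names,
                                         spec$covariate_names),
                   genes = setNames(gene_cols, genes),
                   interactions = setNames(
                     int_cols,
                     vapply(spec$interaction_terms,
                            function(it) paste0(it[1], ":", it[2]),
                            character(1))))
  list(X = X[complete, , drop = FALSE], y = y[complete],
       cluster = factor(study$data$sibship_id[complete],
                        levels = unique(study$data$sibship_id)),
       term_map = term_map, complete = complete)
}

new_phenotype_fit <- function(model, coefficients, covariance, term_map,
                              ...) {
  covariance <- (covariance + t(covariance)) / 2
  dimnames(covariance) <- list(names(coefficients), names(coefficients))
  structure(c(list(model = model, coefficients = coefficients,
                   covariance = covariance, term_map = term_map),
              list(...)),
            class = "phenotype_fit")
}

#' @exportS3Method base::print
print.phenotype_fit <- function(x, ...) {
  cat(sprintf("phenotype_fit (%s): %d coefficients, %d clusters\n",
              x$model, length(x$coefficients), x$n_clusters))
  se <- sqrt(diag(x$covariance))
  print(data.frame(estimate = x$coefficients, se = se,
                   row.names = names(x$coefficients)))
  invisible(x)
}

#' Fit the quantitative-trait linear mixed model
#'
#' Maximum-likelihood fit (REML behind `spec$reml`) of the stage-2 model
#' `y = x'beta + sum_g gamma_g EB_g (+ interactions) + u_sibship + e`, with a
#' normally distributed random sibship effect, via lme4. The model-based
#' covariance of the fixed effects is returned and used for Wald tests. With
#' all-singleton sibships the sibship variance is profiled to the boundary 0
#' and the coefficients coincide with ordinary least squares.
#'
#' @param study a [study_frame()].
#' @param eb EB matrix (subjects x genes).
#' @param spec a [phenotype_model_spec()] with a quantitative trait.
#' @return An object of class `phenotype_fit` (`model = "lmm"`), carrying
#'   `coefficients`, model-based `covariance`, `sibship_variance`,
#'   `residual_variance`, `term_map`, `n_clusters`, `converged`, `loglik`.
#' @export
fit_lmm <- function(study, eb, spec) {
  d <- build_design(study, eb, spec)
  if (!is.null(spec$trait_type) && spec$trait_type != "quantitative")
    np_stop("fit_lmm requires a quantitative trait", "nestpath_design_error")
  if (qr(d$X)$rank < ncol(d$X))
    np_stop("stage-2 design is rank deficient", "nestpath_design_error")
  n_clusters <- nlevels(droplevels(d$cluster))
  if (n_clusters < 2)
    np_stop("need at least 2 sibships", "nestpath_design_error")

  if (max(table(d$cluster)) == 1L) {
    # all-singleton case: sibship and residual variance are confounded;
    # profile sigma2_u to the boundary 0 -> ML = OLS for the coefficients
    fit <- lm(d$y ~ 0 + d$X)
    beta <- setNames(coef(fit), colnames(d$X))
    rss <- sum(fit$residuals^2)
    n <- length(d$y)
    s2 <- if (spec$reml) rss / (n - ncol(d$X)) else rss / n
    V <- s2 * solve(crossprod(d$X))
    return(new_phenotype_fit("lmm", beta, V, d$term_map,
                             sibship_variance = 0, residual_variance = s2,
                             n_clusters = n_clusters, converged = TRUE,
                             loglik = as.numeric(logLik(fit))))
  }

  df <- data.frame(.y = d$y, d$X[, -1, drop = FALSE], check.names = TRUE)
  safe <- names(df)[-1]
  df$.cluster <- d$cluster
  form <- stats::as.formula(paste(".y ~ 1",
                                  if (length(safe))
                                    paste("+", paste(safe, collapse = " + "))
                                  else "",
                                  "+ (1 | .cluster)"))
  lfit <- lme4::lmer(form, data = df, REML = spec$reml,
                     control = lme4::lmerControl(calc.derivs = FALSE))
  beta <- lme4::fixef(lfit)
  names(beta) <- colnames(d$X)            # restore pretty names
  V <- as.matrix(vcov(lfit))
  vc <- lme4::VarCorr(lfit)
  conv <- length(lfit@optinfo$conv$lme4$messages %||% character()) == 0
  new_phenotype_fit("lmm", beta, V, d$term_map,
                    sibship_variance = as.numeric(vc$.cluster[1]),
                    residual_variance = sigma(lfit)^2,
                    n_clusters = n_clusters, converged = conv,
                    loglik = as.numeric(logLik(lfit)))
}

#' Fit the binary-trait logistic GEE
#'
#' Generalized estimating equations for a marginal logistic model with an
#' exchangeable working correlation for subjects within sibships. The
#' working correlation is updated by the Liang-Zeger moment estimator from
#' Pearson residuals, the scale parameter is estimated, and the robust
#' (sandwich) covariance is returned and used for Wald tests. With all
#' clusters of size 1 the estimates reduce to the ordinary logistic MLE and
#' the sandwich to the HC0 heteroscedasticity-robust covariance.
#'
#' @param study a [study_frame()].
#' @param eb EB matrix (subjects x genes).
#' @param spec a [phenotype_model_spec()] with a binary trait.
#' @param tol convergence tolerance on the coefficient change.
#' @param max_iter iteration cap.
#' @return An object of class `phenotype_fit` (`model = "gee"`), carrying
#'   `coefficients`, sandwich `covariance`, `covariance_model_based`,
#'   `working_correlation` (rho), `scale`, `term_map`, `n_clusters`,
#'   `converged`.
#' @export
fit_gee <- function(study, eb, spec, tol = 1e-8, max_iter = 100) {
  d <- build_design(study, eb, spec)
  y <- d$y
  if (!all(y %in% c(0, 1)))
    np_stop("fit_gee requires a binary 0/1 trait", "nestpath_design_error")
  X <- d$X
  p <- ncol(X)
  if (qr(X)$rank < p)
    np_stop("stage-2 design is rank deficient", "nestpath_design_error")
  cl <- droplevels(d$cluster)
  idx <- split(seq_along(y), cl)
  n_clusters <- length(idx)
  sizes <- lengths(idx)
  if (n_clusters < 10)
    np_warn("fewer than 10 clusters: GEE sandwich may be unstable",
            "nestpath_small_sample_warning")

  # separation shows up later as a diverging linear predictor; silence the
  # initializer's own complaints
  beta <- coef(suppressWarnings(glm(y ~ 0 + X, family = binomial())))
  rho <- 0
  phi <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    if (any(abs(eta) > 30))
      np_stop("separation detected: diverging linear predictor",
              "nestpath_separation_error")
    mu <- plogis(eta)
    v <- mu * (1 - mu)
    e <- (y - mu) / sqrt(v)
    phi <- sum(e^2) / (length(y) - p)
    npairs <- sum(sizes * (sizes - 1) / 2)
    if (npairs > p) {
      cp <- sum(vapply(idx, function(ii) {
        ei <- e[ii]
        (sum(ei)^2 - sum(ei^2)) / 2
      }, numeric(1)))
      rho <- cp / ((npairs - p) * phi)
      max_sz <- max(sizes)
      rho <- max(min(rho, 0.999), -1 / (max_sz - 1) + 1e-6)
    } else rho <- 0

    B <- matrix(0, p, p)
    score <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      Xi <- X[ii, , drop = FALSE]
      Ai <- v[ii]
      Di <- Xi * Ai                          # d mu / d beta
      Ri <- matrix(rho, ni, ni); diag(Ri) <- 1
      Vi <- phi * (sqrt(Ai) %o% sqrt(Ai)) * Ri
      Vinv <- solve(Vi)
      B <- B + t(Di) %*% Vinv %*% Di
      score <- score + t(Di) %*% Vinv %*% (y[ii] - mu[ii])
    }
    delta <- solve(B, score)
    beta <- beta + as.numeric(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    np_stop("GEE did not converge", "nestpath_convergence_error")

  eta <- as.numeric(X %*% beta)
  mu <- plogis(eta)
  v <- mu * (1 - mu)
  B <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    Xi <- X[ii, , drop = FALSE]
    Ai <- v[ii]
    Di <- Xi * Ai
    Ri <- matrix(rho, ni, ni); diag(Ri) <- 1
    Vi <- phi * (sqrt(Ai) %o% sqrt(Ai)) * Ri
    Vinv <- solve(Vi)
    ui <- as.numeric(t(Di) %*% Vinv %*% (y[ii] - mu[ii]))
    B <- B + t(Di) %*% Vinv %*% Di
    M <- M + ui %o% ui
  }
  Binv <- solve(B)
  Vrob <- Binv %*% M %*% Binv
  beta <- setNames(as.numeric(beta), colnames(X))
  new_phenotype_fit("gee", beta, Vrob, d$term_map,
                    covariance_model_based = Binv,
                    working_correlation = rho, scale = phi,
                    n_clusters = n_clusters, converged = TRUE,
                    n_iterations = it)
}
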