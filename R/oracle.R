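#' Quadrature oracle for the genotype-model marginal log-likelihood
#'
#' Evaluates the marginal log-likelihood of the nested random-effects
#' binomial genotype model at fixed parameters by nested adaptive
#' Gauss-Hermite quadrature. Because the random effects are nested, the
#' marginal likelihood factorizes into a recursion of one-dimensional
#' integrals (gene within subject, subject within sibship, sibship); each is
#' integrated on nodes centred and scaled at the mode of its integrand.
#' Intended as an independent check of the Laplace approximation on tiny
#' instances; the per-sibship random-effect dimension is capped at 8.
#'
#' @param bundle a [dataset_bundle()].
#' @param parameters list with `fixed_effects` (named numeric, matching the
#'   design implied by `spec`) and `variance_components` (named numeric
#'   `c(sib=, subj=, gene=)`); a [fit_gene_model()] object is also accepted.
#' @param quadrature_points nodes per dimension (default 15).
#' @param spec a [gene_model_spec()] describing the fixed-effect structure.
#' @return The marginal log-likelihood (a scalar).
#' @export
loglik_oracle <- function(bundle, parameters, quadrature_points = 15,
                          spec = NULL) {
  if (inherits(parameters, "gene_model_fit")) {
    spec <- spec %||% parameters$spec
    parameters <- list(fixed_effects = parameters$fixed_effects,
                       variance_components = parameters$variance_components)
  }
  spec <- spec %||% gene_model_spec()
  dat <- build_gene_model_data(bundle, spec)
  beta <- parameters$fixed_effects[dat$fixed_names]
  if (anyNA(beta))
    np_stop("fixed effects do not match the model design",
            "nestpath_design_error")
  vc <- c(sib = 0, subj = 0, gene = 0)
  vc[names(parameters$variance_components)] <-
    parameters$variance_components
  if (!dat$include_sib) vc["sib"] <- 0
  sig <- sqrt(vc)

  eta0 <- as.numeric(dat$X %*% unname(beta))
  gh <- pracma::gaussHermite(quadrature_points)

  # cap: active random-effect dimension per sibship
  for (i in seq_along(dat$sib_levels)) {
    subj_in <- which(dat$sib_of_subj == i)
    dim_i <- (sig["sib"] > 0) + sum(vapply(subj_in, function(jj) {
      cells <- dat$subj == jj
      (sig["subj"] > 0) +
        (if (sig["gene"] > 0) length(unique(dat$gene[cells])) else 0L)
    }, numeric(1)))
    if (dim_i > 8)
      np_stop("per-sibship random-effect dimension exceeds the oracle cap (8)",
              "nestpath_size_error")
  }

  total <- 0
  for (i in seq_along(dat$sib_levels)) {
    subj_in <- which(dat$sib_of_subj == i)
    log_sib <- function(b_i) {
      s <- 0
      for (jj in subj_in) {
        log_subj <- local({
          jj_ <- jj
          function(b_ij) {
            acc <- 0
            for (g in unique(dat$gene[dat$subj == jj_])) {
              cells <- which(dat$subj == jj_ & dat$gene == g)
              log_gene <- local({
                cells_ <- cells
                function(b_ijg) {
                  eta <- eta0[cells_] + b_i + b_ij + b_ijg
                  sum(dbinom(dat$w[cells_], 2, plogis(eta), log = TRUE))
                }
              })
              acc <- acc + log_quad_1d(log_gene, sig[["gene"]], gh)
            }
            acc
          }
        })
        s <- s + log_quad_1d(log_subj, sig[["subj"]], gh)
      }
      s
    }
    total <- total + log_quad_1d(log_sib, sig[["sib"]], gh)
  }
  total
}

# log of integral of exp(logf(b)) * N(b; 0, sigma^2) db by adaptive GH:
# nodes centred at the mode of the log-integrand, scaled by its curvature
log_quad_1d <- function(logf, sigma, gh) {
  if (sigma == 0) return(logf(0))
  logpost <- function(b) logf(b) + dnorm(b, 0, sigma, log = TRUE)
  opt <- stats::optimize(logpost, interval = c(-8 * sigma - 4, 8 * sigma + 4),
                         maximum = TRUE, tol = 1e-10)
  mu <- opt$maximum
  d <- 1e-3 * max(sigma, 1)
  h2 <- (logpost(mu + d) - 2 * opt$objective + logpost(mu - d)) / d^2
  s <- 1 / sqrt(max(-h2, 1e-8))
  y <- mu + sqrt(2) * s * gh$x
  logvals <- vapply(seq_along(y),
                    function(k) logpost(y[k]) + gh$x[k]^2 + log(gh$w[k]),
                    numeric(1))
  m <- max(logvals)
  m + log(sum(exp(logvals - m))) + 0.5 * log(2) + log(s)
}
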