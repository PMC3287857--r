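#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis qlogis pchisq rnorm rbinom runif binomial coef
#'   glm logLik model.matrix vcov dbinom lm sigma complete.cases dnorm sd var
#'   setNames optim
#' @importFrom utils read.table write.table modifyList
#' @import Matrix
NULL

# classed conditions so callers can distinguish failure modes
np_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nestpath_error", "error")))
}

np_warn <- function(msg, class = "nestpath_warning") {
  warning(warningCondition(msg, class = c(class, "warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic, order-insensitive per-replicate seed stream: one LCG step of
# a mixed counter, kept inside the 32-bit signed range set.seed() accepts.
derive_seed <- function(seed, counter) {
  x <- (as.double(seed) %% 2147483647) + 1
  y <- (as.double(counter) %% 2147483647) + 1
  as.integer((48271 * x + 16807 * y) %% 2147483629)
}

# short stable hash of a configuration list (no external digest dependency)
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

fmt_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p < 1e-4, sprintf("%.1e", p), sprintf("%.4f", p)))
}
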