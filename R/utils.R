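# Run code under a temporary RNG state when `seed` is given; otherwise use
# (and advance) the global stream.  Restores .Random.seed on exit so seeded
# calls are free of side effects.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k + 1)/(n - k - 1)`.  Returns `Inf` when
#' `n <= k + 1` (the correction term blows up), which conservatively
#' removes under-sampled fits from model selection.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return The AICc value (scalar).
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Sample CV with the (n - 1) standard-deviation convention used in reports.
sample_cv <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}
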