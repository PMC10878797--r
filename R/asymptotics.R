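#' Inequality index specification
#'
#' The three unitless inequality indices used to summarize damage
#' variability, each characterized by the constant `c` that links it to the
#' coefficient of variation in the normal limit: for a Normal(mu, sigma)
#' distribution the index equals `(sigma/mu)/c`, with `c = 1` (CV),
#' `sqrt(pi)` (Gini) and `sqrt(2*pi)` (Hoover).
#'
#' @param name One of `"CV"`, `"Gini"`, `"Hoover"` (case-insensitive).
#' @return An object of class `"index_spec"` with fields `name` and `c`.
#' @export
index_spec <- function(name = c("CV", "Gini", "Hoover")) {
  name <- match.arg(toupper(name[1L]), c("CV", "GINI", "HOOVER"))
  name <- c(CV = "CV", GINI = "Gini", HOOVER = "Hoover")[[name]]
  cc <- switch(name, CV = 1, Gini = sqrt(pi), Hoover = sqrt(2 * pi))
  structure(list(name = name, c = cc), class = "index_spec")
}

#' Gini coefficient
#'
#' Mean absolute difference between all pairs divided by twice the mean,
#' i.e. `sum_{i,j} |x_i - x_j| / (2 n^2 mean)`, computed by the
#' O(n log n) sorted form.
#'
#' @param x Numeric vector of non-negative values with positive mean.
#' @return The Gini coefficient.
#' @export
gini <- function(x) {
  n <- length(x)
  m <- mean(x)
  if (m == 0) stop("Gini undefined for zero-mean data", call. = FALSE)
  xs <- sort(x)
  sum((2 * seq_len(n) - n - 1) * xs) / (n^2 * m)
}

#' Sample inequality index
#'
#' Exact sample versions of the three indices: CV (`sd/mean`, with the
#' n - 1 standard-deviation convention), Gini (mean absolute pairwise
#' difference over twice the mean) and Hoover (`sum |x - mean| / (2 n mean)`).
#'
#' @param values Numeric vector, length >= 2, with positive mean.
#' @param spec An [index_spec()] or an index name.
#' @return The index value (0 for constant data).
#' @export
sample_index <- function(values, spec = index_spec("CV")) {
  if (is.character(spec)) spec <- index_spec(spec)
  stopifnot(inherits(spec, "index_spec"), length(values) >= 2)
  m <- mean(values)
  if (m <= 0) stop("index undefined for non-positive mean", call. = FALSE)
  if (stats::var(values) == 0) return(0)
  switch(spec$name,
         CV = stats::sd(values) / m,
         Gini = gini(values),
         Hoover = sum(abs(values - m)) / (2 * length(values) * m))
}

#' Large attack-rate approximation of inequality indices
#'
#' For cumulative damage well below 1 and large `lambda`, the compound sum
#' is approximately Normal with mean `lambda E[phi]` and variance
#' `lambda E[phi^2]`, so any of the three indices is approximately
#' `sqrt(E[phi^2]/lambda) / (c E[phi])`: variability declines as
#' `1/sqrt(lambda)` whatever the index.
#'
#' @param model A [neutral_model()] with `lam > 0`.
#' @param spec An [index_spec()] or index name.
#' @return The approximate index value.
#' @export
asymptotic_index <- function(model, spec = index_spec("CV")) {
  if (is.character(spec)) spec <- index_spec(spec)
  stopifnot(inherits(model, "neutral_model"), inherits(spec, "index_spec"))
  if (model$lam <= 0) stop("asymptotic index requires lambda > 0", call. = FALSE)
  e1 <- event_moment(1, model$event)
  e2 <- event_moment(2, model$event)
  sqrt(e2 / model$lam) / (spec$c * e1)
}
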