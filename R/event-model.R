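#' Per-event damage distribution parameters
#'
#' Construct and validate the parameters of the single-feeding-event damage
#' distribution: a truncated Pareto (power law) on `[phi_m, phi_M]` with
#' exponent `alpha`.  The default exponent 14/9 follows from metabolic
#' scaling theory (see [derive_alpha()]); the default bounds are 0.5% (the
#' smallest damage typically recordable by visual estimation) and 100%.
#'
#' @param phi_m Lower bound of per-event proportion damage, in (0, 1).
#' @param phi_M Upper bound of per-event proportion damage, in (`phi_m`, 1].
#' @param alpha Power-law exponent; must differ from 1 (the normalization
#'   constant is undefined at `alpha == 1`).
#' @return An object of class `"event_params"`: a list with elements
#'   `phi_m`, `phi_M`, `alpha`.
#' @examples
#' ep <- event_params()
#' event_moment(1, ep)  # mean per-event damage
#' @export
event_params <- function(phi_m = 0.005, phi_M = 1, alpha = 14 / 9) {
  stopifnot(is.numeric(phi_m), length(phi_m) == 1L,
            is.numeric(phi_M), length(phi_M) == 1L,
            is.numeric(alpha), length(alpha) == 1L)
  if (!(phi_m > 0 && phi_m < phi_M && phi_M <= 1))
    stop("event bounds must satisfy 0 < phi_m < phi_M <= 1", call. = FALSE)
  if (alpha == 1)
    stop("alpha = 1 is not supported (normalization undefined)", call. = FALSE)
  structure(list(phi_m = phi_m, phi_M = phi_M, alpha = alpha),
            class = "event_params")
}

as_event_params <- function(x) {
  if (inherits(x, "event_params")) return(x)
  if (is.list(x) && all(c("phi_m", "phi_M", "alpha") %in% names(x)))
    return(event_params(x$phi_m, x$phi_M, x$alpha))
  stop("not an event_params object", call. = FALSE)
}

#' @export
print.event_params <- function(x, ...) {
  cat(sprintf("Truncated Pareto event distribution on [%g, %g], alpha = %.6g\n",
              x$phi_m, x$phi_M, x$alpha))
  invisible(x)
}

# normalization constant: integral of x^-alpha over [phi_m, phi_M]
.event_norm <- function(p) {
  (p$phi_M^(1 - p$alpha) - p$phi_m^(1 - p$alpha)) / (1 - p$alpha)
}

#' Truncated Pareto event distribution
#'
#' Density, cumulative distribution, quantile function and random sampling
#' for the per-event damage distribution.  The quantile function is the
#' closed-form inverse CDF, which is also how `event_sample()` draws.
#'
#' @param x,q Vector of proportions.
#' @param u Vector of probabilities in `[0, 1]`.
#' @param n Number of draws.
#' @param params An [event_params()] object.
#' @param seed Optional integer seed; the global RNG state is left intact.
#' @return `event_pdf` and `event_cdf` return densities/probabilities
#'   (0 outside the support); `event_quantile` and `event_sample` return
#'   proportions in `[phi_m, phi_M]`.
#' @examples
#' p <- event_params()
#' integrate(event_pdf, p$phi_m, p$phi_M, params = p)$value  # 1
#' @export
event_pdf <- function(x, params) {
  p <- as_event_params(params)
  out <- numeric(length(x))
  ok <- x >= p$phi_m & x <= p$phi_M
  out[ok] <- x[ok]^(-p$alpha) / .event_norm(p)
  out
}

#' @rdname event_pdf
#' @export
event_cdf <- function(q, params) {
  p <- as_event_params(params)
  out <- numeric(length(q))
  out[q >= p$phi_M] <- 1
  mid <- q > p$phi_m & q < p$phi_M
  out[mid] <- (q[mid]^(1 - p$alpha) - p$phi_m^(1 - p$alpha)) /
    (p$phi_M^(1 - p$alpha) - p$phi_m^(1 - p$alpha))
  out
}

#' @rdname event_pdf
#' @export
event_quantile <- function(u, params) {
  p <- as_event_params(params)
  if (any(u < 0 | u > 1, na.rm = TRUE))
    stop("quantile levels must lie in [0, 1]", call. = FALSE)
  a1 <- 1 - p$alpha
  (p$phi_m^a1 + u * (p$phi_M^a1 - p$phi_m^a1))^(1 / a1)
}

#' @rdname event_pdf
#' @export
event_sample <- function(n, params, seed = NULL) {
  with_seed(seed, event_quantile(stats::runif(n), params))
}

#' Closed-form moments of the event distribution
#'
#' The n-th raw moment of the truncated Pareto event distribution,
#' `E[phi^n] = ((1 - alpha)/(n + 1 - alpha)) *
#' (phi_M^(n+1-alpha) - phi_m^(n+1-alpha)) / (phi_M^(1-alpha) - phi_m^(1-alpha))`.
#' The first two moments drive the normal-limit inequality-index
#' approximation ([asymptotic_index()]).
#'
#' @param n Moment order (positive integer); `n + 1 - alpha` must be nonzero.
#' @param params An [event_params()] object.
#' @return The raw moment, a scalar.
#' @export
event_moment <- function(n, params) {
  p <- as_event_params(params)
  stopifnot(length(n) == 1L, n >= 1)
  if (n + 1 - p$alpha == 0)
    stop("moment undefined: n + 1 - alpha = 0", call. = FALSE)
  a1 <- 1 - p$alpha
  ((a1) / (n + a1)) * (p$phi_M^(n + a1) - p$phi_m^(n + a1)) /
    (p$phi_M^a1 - p$phi_m^a1)
}

#' Derive the event-size exponent from allometric scaling laws
#'
#' If per-event consumption scales with herbivore body mass as `M^a`, the
#' population density of a species as `M^b`, and species richness as `M^c`,
#' then the probability that a randomly sampled feeding event comes from a
#' herbivore of mass `M` is proportional to `M^(b + c)`.  A change of
#' variables from mass to per-event damage `phi` (proportional to `M^a`)
#' gives `P(phi)` proportional to `phi^(-alpha)` with
#' `alpha = (a - 1 - b - c) / a`.  The canonical metabolic-theory triple
#' `a = 3/4` (Kleiber consumption), `b = -3/4` (energetic-equivalence
#' density), `c = -2/3` (size-richness scaling) yields `alpha = 14/9`, the
#' package default.
#'
#' @param metabolic_exponent Exponent `a` of consumption on body mass
#'   (must be nonzero).
#' @param density_exponent Exponent `b` of population density on body mass.
#' @param richness_exponent Exponent `c` of species richness on body mass.
#' @return The power-law exponent `alpha`.
#' @examples
#' derive_alpha(3/4, -3/4, -2/3)  # 14/9
#' @export
derive_alpha <- function(metabolic_exponent, density_exponent,
                         richness_exponent) {
  a <- metabolic_exponent
  if (a == 0) stop("metabolic exponent must be nonzero", call. = FALSE)
  (a - 1 - density_exponent - richness_exponent) / a
}
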