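#' Hurdle truncated lognormal log-density
#'
#' The hurdle truncated lognormal (HTLN) distribution places probability
#' `p0` at exactly 0 and distributes the rest as a lognormal partitioned at
#' 1: values in (0, 1) keep the lognormal density `g(x; mu, sigma)` and all
#' lognormal mass at or above 1 collapses into an atom at exactly 1 with
#' probability `(1 - p0) (1 - G(1; mu, sigma))`.
#'
#' @param x Vector of proportions in `[0, 1]`.
#' @param params List with `p0` (in `[0, 1]`), `mu` (log-scale location)
#'   and `sigma` (log-scale sd, > 0).
#' @return Log density/mass at each `x`.
#' @export
htln_logpdf <- function(x, params) {
  stopifnot(params$p0 >= 0, params$p0 <= 1, params$sigma > 0)
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]", call. = FALSE)
  out <- numeric(length(x))
  z <- x == 0
  o <- x == 1
  i <- !z & !o
  out[z] <- log(params$p0)
  out[o] <- log1p(-params$p0) +
    stats::plnorm(1, params$mu, params$sigma, lower.tail = FALSE, log.p = TRUE)
  out[i] <- log1p(-params$p0) +
    stats::dlnorm(x[i], params$mu, params$sigma, log = TRUE)
  out
}

#' Zero-one-inflated beta log-density
#'
#' Atoms `p0` at 0 and `p1` at 1 (two independent inflation fractions),
#' with the remaining mass `1 - p0 - p1` beta-distributed on (0, 1) in the
#' mean/precision parameterization (`shape1 = mu * prec`,
#' `shape2 = (1 - mu) * prec`).
#'
#' @param x Vector of proportions in `[0, 1]`.
#' @param params List with `p0`, `p1` (non-negative, `p0 + p1 <= 1`),
#'   `mu` in (0, 1) and `prec` > 0.
#' @return Log density/mass at each `x`.
#' @export
zoib_logpdf <- function(x, params) {
  stopifnot(params$p0 >= 0, params$p1 >= 0, params$p0 + params$p1 <= 1,
            params$mu > 0, params$mu < 1, params$prec > 0)
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]", call. = FALSE)
  out <- numeric(length(x))
  z <- x == 0
  o <- x == 1
  i <- !z & !o
  out[z] <- log(params$p0)
  out[o] <- log(params$p1)
  out[i] <- log(1 - params$p0 - params$p1) +
    stats::dbeta(x[i], params$mu * params$prec,
                 (1 - params$mu) * params$prec, log = TRUE)
  out
}

# shared atom bookkeeping for the hurdle/inflation factorizations
.xlogp <- function(m, p) if (m == 0) 0 else m * log(p)

# interval-censored interior log-likelihood under a continuous CDF `pfun`
.censored_ll <- function(y, precision, mode, pfun, dfun) {
  if (mode == "interval") {
    lo <- pmax(y - precision / 2, 0)
    hi <- pmin(y + precision / 2, 1)
    band <- pfun(hi) - pfun(lo)
    sum(log(pmax(band, 1e-300)))
  } else {
    sum(dfun(y))
  }
}

#' Fit the hurdle truncated lognormal by maximum likelihood
#'
#' The atom probability `p0` is the empirical fraction of exact 0s (its MLE
#' under the hurdle factorization); `mu` and `sigma` are estimated
#' numerically from the interior values and the exact 1s.  Interior values
#' use the same interval-censoring convention as [fit_neutral()] so that
#' AICc values are comparable across models.
#'
#' @param data Numeric vector of proportions in `[0, 1]`.
#' @param precision,mode As in [loglik_neutral()].
#' @return An object of class `"alt_fit"` with `model = "htln"`, `params`,
#'   `loglik`, `n`, `aicc` (k = 3) and `flags`.
#' @export
fit_htln <- function(data, precision = 0.005,
                     mode = c("interval", "density")) {
  mode <- match.arg(mode)
  if (any(data < 0 | data > 1)) stop("data must lie in [0, 1]", call. = FALSE)
  n <- length(data)
  n0 <- sum(data == 0)
  n1 <- sum(data == 1)
  y <- data[data > 0 & data < 1]
  p0 <- n0 / n
  ll <- .xlogp(n0, p0) + .xlogp(n - n0, 1 - p0)
  flags <- character()
  mu <- sigma <- NA_real_
  if (length(y) == 0) {
    # no interior data: the lognormal component is unidentifiable; its
    # supremum pushes all non-zero mass onto the atom at 1
    flags <- "interior_unidentifiable"
  } else {
    mu0 <- mean(log(y))
    s0 <- if (length(y) > 1) stats::sd(log(y)) else 0.5
    if (!is.finite(s0) || s0 <= 0) s0 <- 0.5
    nll <- function(th) {
      m <- th[1]; s <- exp(th[2])
      v <- n1 * stats::plnorm(1, m, s, lower.tail = FALSE, log.p = TRUE) +
        .censored_ll(y, precision, mode,
                     function(x) stats::plnorm(x, m, s),
                     function(x) stats::dlnorm(x, m, s, log = TRUE))
      if (!is.finite(v)) return(1e10)
      -v
    }
    opt <- stats::optim(c(mu0, log(s0)), nll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (opt$convergence != 0) flags <- c(flags, "optim_nonconvergence")
    mu <- opt$par[1]; sigma <- exp(opt$par[2])
    ll <- ll - opt$value
  }
  structure(list(model = "htln",
                 params = list(p0 = p0, mu = mu, sigma = sigma),
                 loglik = ll, n = n, aicc = aicc(ll, 3, n), k = 3L,
                 flags = flags, precision = precision, mode = mode),
            class = "alt_fit")
}

#' Fit the zero-one-inflated beta by maximum likelihood
#'
#' `p0` and `p1` are the empirical fractions of exact 0s and 1s (their MLEs
#' under the two-atom factorization); the beta mean and precision are
#' estimated numerically from interior values with the shared
#' interval-censoring convention.
#'
#' @inheritParams fit_htln
#' @return An `"alt_fit"` with `model = "zoib"`, `aicc` (k = 4).
#' @export
fit_zoib <- function(data, precision = 0.005,
                     mode = c("interval", "density")) {
  mode <- match.arg(mode)
  if (any(data < 0 | data > 1)) stop("data must lie in [0, 1]", call. = FALSE)
  n <- length(data)
  n0 <- sum(data == 0)
  n1 <- sum(data == 1)
  y <- data[data > 0 & data < 1]
  p0 <- n0 / n
  p1 <- n1 / n
  ll <- .xlogp(n0, p0) + .xlogp(n1, p1) + .xlogp(length(y), 1 - p0 - p1)
  flags <- character()
  mu <- prec <- NA_real_
  if (length(y) == 0) {
    flags <- "interior_unidentifiable"
  } else {
    mb <- mean(y)
    vb <- if (length(y) > 1) stats::var(y) else 0
    prec0 <- if (vb > 0) max(mb * (1 - mb) / vb - 1, 0.1) else 10
    nll <- function(th) {
      m <- stats::plogis(th[1]); s <- exp(th[2])
      v <- .censored_ll(y, precision, mode,
                        function(x) stats::pbeta(x, m * s, (1 - m) * s),
                        function(x) stats::dbeta(x, m * s, (1 - m) * s,
                                                 log = TRUE))
      if (!is.finite(v)) return(1e10)
      -v
    }
    opt <- stats::optim(c(stats::qlogis(mb), log(prec0)), nll,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10))
    if (opt$convergence != 0) flags <- c(flags, "optim_nonconvergence")
    mu <- stats::plogis(opt$par[1]); prec <- exp(opt$par[2])
    ll <- ll - opt$value
  }
  structure(list(model = "zoib",
                 params = list(p0 = p0, p1 = p1, mu = mu, prec = prec),
                 loglik = ll, n = n, aicc = aicc(ll, 4, n), k = 4L,
                 flags = flags, precision = precision, mode = mode),
            class = "alt_fit")
}

#' @export
print.alt_fit <- function(x, ...) {
  cat(sprintf("%s fit: loglik = %.4f, n = %d, k = %d, AICc = %.4f\n",
              toupper(x$model), x$loglik, x$n, x$k, x$aicc))
  invisible(x)
}

#' AICc difference between a competitor and the neutral fit
#'
#' `delta_aicc = AICc(alternative) - AICc(neutral)`: positive values favour
#' the neutral model.  Both fits must be on the same data with the same
#' censoring convention, otherwise the difference is meaningless.
#'
#' @param alt_fit An [fit_htln()] or [fit_zoib()] result.
#' @param neutral_fit A [fit_neutral()] result.
#' @return The AICc difference (scalar).
#' @export
delta_aicc <- function(alt_fit, neutral_fit) {
  stopifnot(inherits(neutral_fit, "neutral_fit"))
  if (alt_fit$n != neutral_fit$n)
    stop("fits compare different numbers of observations", call. = FALSE)
  alt_fit$aicc - neutral_fit$aicc
}
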