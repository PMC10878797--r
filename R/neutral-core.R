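#' Neutral herbivory model
#'
#' Bundle an attack rate `lam` (expected feeding events per leaf, or per
#' plant at the plant scale) with an event distribution.  Cumulative damage
#' is the Poisson(`lam`)-count sum of independent truncated-Pareto event
#' damages, truncated at 1 once a leaf is fully consumed.
#'
#' @param lam Attack rate, >= 0.
#' @param event An [event_params()] object.
#' @return An object of class `"neutral_model"`.
#' @export
neutral_model <- function(lam, event = event_params()) {
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0)
  structure(list(lam = lam, event = as_event_params(event)),
            class = "neutral_model")
}

#' @export
print.neutral_model <- function(x, ...) {
  cat(sprintf("Neutral damage model: lambda = %.6g, events on [%g, %g], alpha = %.4g\n",
              x$lam, x$event$phi_m, x$event$phi_M, x$event$alpha))
  invisible(x)
}

#' Simulate cumulative proportion damage
#'
#' For each draw, the number of feeding events is Poisson(`lam`); cumulative
#' damage is the sum of that many independent event damages, truncated at 1.
#' Zero events give exactly 0 damage.
#'
#' @param model A [neutral_model()].
#' @param n Number of leaves (or plants) to simulate.
#' @param seed Optional integer seed; global RNG state is restored.
#' @return Numeric vector of `n` proportions in `[0, 1]`.
#' @export
simulate_damage <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "neutral_model"), n >= 1)
  with_seed(seed, {
    k <- stats::rpois(n, model$lam)
    out <- numeric(n)
    total <- sum(k)
    if (total > 0) {
      phis <- event_quantile(stats::runif(total), model$event)
      idx <- rep.int(seq_len(n), k)
      sums <- rowsum(phis, idx)
      out[as.integer(rownames(sums))] <- sums[, 1L]
    }
    pmin(out, 1)
  })
}

# --- lattice machinery -----------------------------------------------------
# Damage values are represented on the lattice x_j = j*h, j = 1..N, h = 1/N;
# entry j holds the probability mass of the cell ((j-1)h, jh].  k-fold event
# sums are built by FFT convolution on this lattice; mass at lattice index
# > N has surely exceeded full consumption and is accumulated into the atom
# at 1.

.event_lattice <- function(event, grid_size) {
  h <- 1 / grid_size
  edges <- seq_len(grid_size) * h
  q <- diff(c(0, event_cdf(edges, event)))
  q
}

# Table of in-range k-fold convolution masses.  Stops once the in-range
# (damage < 1) mass of the k-fold sum is below mass_tol: every later event
# count lands in the atom at 1 almost surely.  Convolutions are done by FFT
# on a power-of-two padding (lattice sums only grow, so truncating the
# out-of-range part at each step is exact for the in-range part).
.kfold_table <- function(event, grid_size, mass_tol = 1e-12,
                         max_k = 100000L) {
  q <- .event_lattice(event, grid_size)
  N <- grid_size
  len <- 2L * N  # power of two when grid_size is
  fq <- stats::fft(c(q, numeric(len - N)))
  masses <- list(q)
  cur <- q
  k <- 1L
  while (sum(cur) >= mass_tol && k < max_k) {
    fc <- stats::fft(c(cur, numeric(len - N)))
    full <- Re(stats::fft(fc * fq, inverse = TRUE)) / len
    # full[m] holds lattice index s = m + 1 (s in 2..2N)
    new <- c(0, full[seq_len(N - 1L)])
    new[new < 0] <- 0  # FFT round-off
    k <- k + 1L
    masses[[k]] <- new
    cur <- new
  }
  list(masses = masses, K = k, grid_size = grid_size, event = event)
}

#' Numerical distribution of cumulative damage
#'
#' Build the mixed distribution of cumulative proportion damage: a point
#' mass `p0 = exp(-lam)` at exactly 0 (no feeding events), a point mass
#' `p1` at exactly 1 (full consumption), and a continuous density on
#' (0, 1) computed as the Poisson-weighted sum of k-fold convolutions of
#' the discretized event density.  The k-summation stops when the remaining
#' Poisson tail falls below `poisson_tail_tol`; that tail, and all event
#' counts whose sum exceeds 1 almost surely, are assigned to the atom at 1.
#'
#' @param model A [neutral_model()].
#' @param grid_size Number of lattice cells on (0, 1] (>= 256; default 4096).
#' @param poisson_tail_tol Neglected Poisson tail probability, folded into
#'   the atom at 1.
#' @param table Optional precomputed convolution table (internal use by
#'   [fit_neutral()]).
#' @return An object of class `"mixed_damage_distribution"` with fields
#'   `p0`, `p1`, `grid` (cell midpoints), `density` (continuous density,
#'   normalized so that `p0 + p1 +` trapezoid integral `= 1`), and the
#'   underlying cell masses.
#' @export
damage_distribution <- function(model, grid_size = 4096,
                                poisson_tail_tol = 1e-10, table = NULL) {
  stopifnot(inherits(model, "neutral_model"), grid_size >= 256)
  lam <- model$lam
  if (is.null(table)) {
    table <- .kfold_table(model$event, grid_size)
  } else {
    stopifnot(table$grid_size == grid_size)
  }
  N <- grid_size
  h <- 1 / N
  p0 <- exp(-lam)
  cell_mass <- numeric(N)
  if (lam > 0) {
    k_tail <- stats::qpois(poisson_tail_tol, lam, lower.tail = FALSE) + 1L
    k_use <- min(table$K, k_tail)
    w <- stats::dpois(seq_len(k_use), lam)
    for (k in seq_len(k_use)) {
      if (w[k] > 0) cell_mass <- cell_mass + w[k] * table$masses[[k]]
    }
  }
  interior <- sum(cell_mass)
  p1 <- max(0, 1 - p0 - interior)
  dens <- cell_mass / h
  # renormalize so the reported trapezoid integral matches the interior mass
  mids <- (seq_len(N) - 0.5) * h
  trap <- h * (sum(dens) - (dens[1L] + dens[N]) / 2)
  if (trap > 0) dens <- dens * (interior / trap)
  structure(list(p0 = p0, p1 = p1, grid = mids, density = dens,
                 cell_mass = cell_mass, h = h, lam = lam,
                 event = model$event),
            class = "mixed_damage_distribution")
}

#' @export
print.mixed_damage_distribution <- function(x, ...) {
  cat(sprintf(
    "Mixed damage distribution (lambda = %.4g): P(0) = %.4g, P(1) = %.4g, interior mass = %.4g\n",
    x$lam, x$p0, x$p1, sum(x$cell_mass)))
  invisible(x)
}

# continuous-part CDF (excludes both atoms), linear within cells
.cont_cdf <- function(dist, x) {
  N <- length(dist$cell_mass)
  h <- dist$h
  cm <- c(0, cumsum(dist$cell_mass))
  x <- pmin(pmax(x, 0), 1)
  j <- pmin(floor(x / h), N - 1)
  frac <- x / h - j
  cm[j + 1L] + frac * dist$cell_mass[j + 1L]
}

#' Cumulative distribution function of a mixed damage distribution
#'
#' `P(damage <= x)`, including the point masses at 0 and 1.
#'
#' @param dist A `"mixed_damage_distribution"`.
#' @param x Vector of proportions in `[0, 1]`.
#' @return Probabilities.
#' @export
mixed_cdf <- function(dist, x) {
  stopifnot(inherits(dist, "mixed_damage_distribution"))
  out <- ifelse(x < 0, 0, dist$p0 + .cont_cdf(dist, x))
  out[x >= 1] <- 1
  out
}

#' Mean and coefficient of variation of a mixed damage distribution
#'
#' Computed from the atoms and the lattice masses (cell values taken at the
#' right cell edge, consistent with the truncation construction).
#'
#' @param dist A `"mixed_damage_distribution"`.
#' @return A scalar.
#' @export
distribution_mean <- function(dist) {
  xj <- seq_along(dist$cell_mass) * dist$h
  sum(dist$cell_mass * xj) + dist$p1
}

#' @rdname distribution_mean
#' @export
distribution_cv <- function(dist) {
  xj <- seq_along(dist$cell_mass) * dist$h
  m1 <- sum(dist$cell_mass * xj) + dist$p1
  m2 <- sum(dist$cell_mass * xj^2) + dist$p1
  if (m1 <= 0) return(NA_real_)
  sqrt(max(0, m2 - m1^2)) / m1
}

#' Log-likelihood of damage data under the neutral model
#'
#' Exact 0s contribute `log p0` and exact 1s `log p1`.  Interior values are
#' handled, by default, as interval-censored observations: each contributes
#' the log-probability of a band of width `precision` centred on the
#' recorded value (clipped to (0, 1)), computed from the numerical CDF.
#' This matches data recorded by visual estimation at a fixed resolution
#' (default 0.5%) and is robust to recorded values below the lower event
#' bound.  `mode = "density"` instead uses the log interpolated density,
#' appropriate for continuous (unrounded) data.
#'
#' @param data Numeric vector of proportions in `[0, 1]`.
#' @param model A [neutral_model()].
#' @param precision Width of the censoring band (> 0; default 0.005).
#' @param mode `"interval"` (default) or `"density"`.
#' @param dist Optional precomputed [damage_distribution()] for `model`.
#' @param grid_size,poisson_tail_tol Passed to [damage_distribution()].
#' @return The log-likelihood; `-Inf` (with a warning) if any observation
#'   falls in a zero-probability band.
#' @export
loglik_neutral <- function(data, model, precision = 0.005,
                           mode = c("interval", "density"), dist = NULL,
                           grid_size = 4096, poisson_tail_tol = 1e-10) {
  mode <- match.arg(mode)
  if (any(data < 0 | data > 1)) stop("data must lie in [0, 1]", call. = FALSE)
  stopifnot(precision > 0)
  if (is.null(dist))
    dist <- damage_distribution(model, grid_size, poisson_tail_tol)
  n0 <- sum(data == 0)
  n1 <- sum(data == 1)
  y <- data[data > 0 & data < 1]
  ll <- 0
  if (n0 > 0) ll <- ll + n0 * log(dist$p0)
  if (n1 > 0) ll <- ll + if (dist$p1 > 0) n1 * log(dist$p1) else -Inf
  if (length(y)) {
    if (mode == "interval") {
      lo <- pmax(y - precision / 2, 0)
      hi <- pmin(y + precision / 2, 1)
      band <- .cont_cdf(dist, hi) - .cont_cdf(dist, lo)
      if (any(band <= 0)) {
        warning("observation(s) in a zero-probability band; log-likelihood is -Inf")
        return(-Inf)
      }
      ll <- ll + sum(log(band))
    } else {
      d <- stats::approx(dist$grid, dist$density, xout = y, rule = 2)$y
      if (any(d <= 0)) {
        warning("observation(s) at zero density; log-likelihood is -Inf")
        return(-Inf)
      }
      ll <- ll + sum(log(d))
    }
  }
  if (is.nan(ll)) ll <- -Inf
  ll
}

#' Maximum-likelihood estimate of the attack rate
#'
#' Fits the single free parameter of the neutral model, the attack rate
#' `lambda`, by bounded one-dimensional maximization of the
#' (interval-censored) log-likelihood on the log scale.  The convolution
#' table of the event distribution is computed once and reused across
#' likelihood evaluations.  After convergence, the log-likelihood is
#' re-evaluated on a doubled lattice; if it moves by more than `1e-3` per
#' observation the fit is repeated on the finer grid (up to two
#' refinements).
#'
#' @param data Numeric vector of proportions in `[0, 1]`.
#' @param event An [event_params()] object.
#' @param precision,mode As in [loglik_neutral()].
#' @param grid_size Initial lattice size.
#' @param lower,upper Optimization bracket for `lambda`.
#' @param poisson_tail_tol As in [damage_distribution()].
#' @return An object of class `"neutral_fit"`: `lam_hat`, `loglik`, `n`,
#'   `aicc` (with k = 1), `flags` (character vector, e.g. `"degenerate"`
#'   for all-zero data), plus the settings used.
#' @export
fit_neutral <- function(data, event = event_params(), precision = 0.005,
                        mode = c("interval", "density"), grid_size = 4096,
                        lower = 1e-4, upper = 1e3,
                        poisson_tail_tol = 1e-10) {
  mode <- match.arg(mode)
  if (length(data) < 1) stop("need at least one observation", call. = FALSE)
  if (any(data < 0 | data > 1)) stop("data must lie in [0, 1]", call. = FALSE)
  n <- length(data)
  if (all(data == 0)) {
    ll <- -n * lower
    return(structure(list(lam_hat = lower, loglik = ll, n = n,
                          aicc = aicc(ll, 1, n), k = 1L,
                          flags = "degenerate", event = as_event_params(event),
                          precision = precision, mode = mode,
                          grid_size = grid_size),
                     class = "neutral_fit"))
  }
  event <- as_event_params(event)
  fit_at <- function(gs) {
    tab <- .kfold_table(event, gs)
    obj <- function(loglam) {
      m <- neutral_model(exp(loglam), event)
      d <- damage_distribution(m, gs, poisson_tail_tol, table = tab)
      loglik_neutral(data, m, precision, mode, dist = d)
    }
    opt <- suppressWarnings(
      stats::optimize(obj, interval = log(c(lower, upper)),
                      maximum = TRUE, tol = 1e-6))
    list(lam = exp(opt$maximum), ll = opt$objective)
  }
  gs <- grid_size
  res <- fit_at(gs)
  for (i in 1:2) {
    ll2 <- suppressWarnings(loglik_neutral(
      data, neutral_model(res$lam, event), precision, mode,
      grid_size = 2L * gs, poisson_tail_tol = poisson_tail_tol))
    if (is.finite(ll2) && is.finite(res$ll) &&
        abs(ll2 - res$ll) < 1e-3 * n) break
    gs <- 2L * gs
    res <- fit_at(gs)
  }
  flags <- character()
  if (res$lam <= lower * 1.01) flags <- c(flags, "at_lower_bound")
  if (res$lam >= upper * 0.99) flags <- c(flags, "at_upper_bound")
  structure(list(lam_hat = res$lam, loglik = res$ll, n = n,
                 aicc = aicc(res$ll, 1, n), k = 1L, flags = flags,
                 event = event, precision = precision, mode = mode,
                 grid_size = gs),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat(sprintf("Neutral fit: lambda-hat = %.5g  (loglik = %.4f, n = %d, AICc = %.4f)\n",
              x$lam_hat, x$loglik, x$n, x$aicc))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Closed-form attack-rate estimate from presence/absence of damage
#'
#' Under the neutral model the probability that a leaf shows any damage is
#' `1 - exp(-lambda)`, so the maximum-likelihood estimate from a binary
#' damaged/undamaged summary is `lambda-hat = -log(1 - n_damaged/n_total)`.
#'
#' @param n_damaged Number of units with any damage.
#' @param n_total Total number of units.
#' @return A `"neutral_fit"` with the Bernoulli log-likelihood and AICc
#'   (k = 1).  If every unit is damaged the estimate is infinite and the
#'   fit is flagged `"at_upper_bound"`.
#' @export
fit_presence_absence <- function(n_damaged, n_total) {
  stopifnot(n_total >= 1, n_damaged >= 0, n_damaged <= n_total)
  phat <- n_damaged / n_total
  flags <- character()
  if (n_damaged == n_total) {
    lam <- Inf
    flags <- "at_upper_bound"
  } else {
    lam <- -log(1 - phat)
  }
  xlogx <- function(m, p) if (m == 0) 0 else m * log(p)
  ll <- xlogx(n_total - n_damaged, 1 - phat) + xlogx(n_damaged, phat)
  structure(list(lam_hat = lam, loglik = ll, n = n_total,
                 aicc = aicc(ll, 1, n_total), k = 1L, flags = flags,
                 event = NULL, precision = NA_real_, mode = "binary",
                 grid_size = NA_integer_),
            class = "neutral_fit")
}

#' Rescale event bounds from the leaf to the plant scale
#'
#' At the plant scale a single feeding event removes a fraction of the whole
#' plant's leaf area, so both event bounds are divided by `L`, the (median)
#' number of leaves per plant; the exponent is unchanged and cumulative
#' damage still truncates at 1.
#'
#' @param event An [event_params()] object (leaf-scale bounds).
#' @param L Leaves per plant, >= 1 (see [median_leaves()]).
#' @return An [event_params()] object with bounds divided by `L`.
#' @export
plant_scale_event_params <- function(event, L) {
  stopifnot(is.numeric(L), length(L) == 1L, L >= 1)
  event <- as_event_params(event)
  event_params(event$phi_m / L, event$phi_M / L, event$alpha)
}
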