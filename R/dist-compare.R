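#' Kolmogorov-Smirnov distance between a sample and a mixed distribution
#'
#' Supremum distance between the empirical CDF and the CDF of a
#' [damage_distribution()], evaluated at the sample values with correct
#' handling of the point masses at 0 and 1 (left limits are compared with
#' the model's left limits).
#'
#' @param x Numeric sample in `[0, 1]`.
#' @param dist A `"mixed_damage_distribution"`.
#' @return The KS distance in `[0, 1]`.
#' @export
ks_distance <- function(x, dist) {
  xs <- sort(unique(x))
  Fm <- mixed_cdf(dist, xs)
  Fe <- stats::ecdf(x)(xs)
  Fe_left <- c(0, Fe[-length(Fe)])
  atom <- ifelse(xs == 0, dist$p0, ifelse(xs == 1, dist$p1, 0))
  max(pmax(abs(Fe - Fm), abs(Fe_left - (Fm - atom))))
}

#' Monte-Carlo-averaged two-sample KS comparison
#'
#' Simulates `n_rep` predicted samples of the observed sample size from the
#' fitted neutral model and runs a two-sample KS test against the observed
#' data for each; the statistic and p-value are averaged across replicates
#' and the fraction of replicates with p < 0.05 is reported.  The p-values
#' use the asymptotic two-sample formula and are approximate in the
#' presence of ties (data recorded on a 0.5% grid are heavily tied).
#'
#' @param observed Numeric vector of proportions.
#' @param fit A [fit_neutral()] result.
#' @param n_rep Number of predicted replicates (default 100).
#' @param seed Optional integer seed.
#' @return A list: `ks_stat` (mean statistic), `ks_p` (mean p-value),
#'   `frac_signif` (fraction of replicates with p < 0.05), plus the
#'   per-replicate vectors `stats` and `pvals`.
#' @export
ks_compare <- function(observed, fit, n_rep = 100, seed = NULL) {
  stopifnot(length(observed) >= 1, inherits(fit, "neutral_fit"))
  model <- neutral_model(fit$lam_hat, fit$event)
  with_seed(seed, {
    stats_v <- pvals <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      pred <- simulate_damage(model, length(observed))
      kt <- suppressWarnings(stats::ks.test(observed, pred))
      stats_v[r] <- unname(kt$statistic)
      pvals[r] <- kt$p.value
    }
    list(ks_stat = mean(stats_v), ks_p = mean(pvals),
         frac_signif = mean(pvals < 0.05),
         stats = stats_v, pvals = pvals, n_rep = n_rep)
  })
}

#' Ten statistical probes of a distribution
#'
#' Summary statistics characterizing distribution shape: mean, variance,
#' skew, kurtosis (non-excess), minimum, maximum, the three quartiles and
#' the Gini coefficient.  Moments are central moments with denominator `n`
#' (skew `m3/m2^1.5`, kurtosis `m4/m2^2`); quantiles use the
#' median-unbiased interpolation convention (`type = 8`).
#'
#' @param values Numeric vector, length >= 2.
#' @return A named numeric vector of length 10 (class `"probe_vector"`).
#'   Zero-variance input yields `NaN` skew/kurtosis and is flagged via the
#'   `"degenerate"` attribute; zero-mean input additionally yields `NA`
#'   Gini.
#' @export
probes <- function(values) {
  stopifnot(length(values) >= 2)
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  g <- if (m > 0) gini(values) else NA_real_
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 8, names = FALSE)
  out <- c(mean = m, variance = m2, skew = m3 / m2^1.5,
           kurtosis = m4 / m2^2, minimum = min(values),
           maximum = max(values), q25 = q[1], q50 = q[2], q75 = q[3],
           gini = g)
  attr(out, "degenerate") <- m2 == 0
  class(out) <- c("probe_vector", "numeric")
  out
}

#' Constrained variance partition of probe matrices
#'
#' How much of the variation in the ten probes is attributable to whether a
#' distribution is observed or model-predicted.  Probe columns are
#' standardized (Z-scores); if a conditioning factor is supplied (e.g.
#' survey identity), the standardized matrix is residualized on it first.
#' With a single binary constraint the redundancy-analysis constrained R^2
#' reduces to the between-group sum of squares over the total (remaining)
#' sum of squares, which is what is computed here.  A permutation null
#' (labels permuted within conditioning strata) gives a reference
#' distribution for the R^2.
#'
#' @param probe_matrix Numeric matrix, one row per distribution, one column
#'   per probe.
#' @param groups Factor/vector with two levels (observed/predicted), one
#'   per row.
#' @param condition Optional conditioning factor (one per row), removed
#'   before partitioning.
#' @param n_perm Number of label permutations for the null (0 to skip).
#' @param seed Optional integer seed for the permutations.
#' @return A list: `r2`, `perm` (null R^2 values), `p_value`
#'   (permutation p), `dropped` (names of zero-variance columns removed).
#' @export
probe_variance_partition <- function(probe_matrix, groups, condition = NULL,
                                     n_perm = 999, seed = NULL) {
  X <- as.matrix(probe_matrix)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, nrow(X) == length(groups),
            all(table(groups) >= 2))
  keep <- apply(X, 2, function(col) stats::var(col) > 0 && all(is.finite(col)))
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    warning("dropping zero-variance or non-finite probe column(s): ",
            paste(dropped, collapse = ", "))
  X <- scale(X[, keep, drop = FALSE])
  if (!is.null(condition)) {
    condition <- as.factor(condition)
    mm <- stats::model.matrix(~condition)
    X <- stats::resid(stats::lm.fit(mm, X))
  }
  r2_of <- function(g) {
    grand <- colMeans(X)
    ss_tot <- sum(sweep(X, 2, grand)^2)
    if (ss_tot == 0) return(0)
    ss_b <- 0
    for (lev in levels(groups)) {
      rows <- g == lev
      ss_b <- ss_b + sum(rows) * sum((colMeans(X[rows, , drop = FALSE]) - grand)^2)
    }
    ss_b / ss_tot
  }
  r2 <- r2_of(groups)
  perm <- numeric(0)
  p_value <- NA_real_
  if (n_perm > 0) {
    perm <- with_seed(seed, {
      strata <- if (is.null(condition)) rep(1L, length(groups)) else condition
      idx_by <- split(seq_along(groups), strata)
      vapply(seq_len(n_perm), function(i) {
        g <- groups
        for (ii in idx_by) g[ii] <- g[sample(ii)]
        r2_of(g)
      }, numeric(1))
    })
    p_value <- (1 + sum(perm >= r2)) / (n_perm + 1)
  }
  list(r2 = r2, perm = perm, p_value = p_value, dropped = dropped)
}

#' Observed-versus-predicted CV regression
#'
#' Simple-regression r^2 and major-axis (model II) regression of
#' log-observed on log-predicted CVs across datasets.  The major-axis slope
#' is the slope of the leading eigenvector of the 2x2 covariance matrix of
#' the log pairs; the intercept passes through the means.  Confidence
#' intervals are percentile bootstrap over pairs.
#'
#' @param observed_cvs,predicted_cvs Paired positive CVs; non-finite or
#'   non-positive pairs (zero-variance datasets) are excluded.
#' @param n_boot Bootstrap resamples (default 1999).
#' @param seed Optional integer seed.
#' @return A list: `r2`, `slope`, `intercept`, `slope_ci`, `intercept_ci`,
#'   `n` (pairs used), `n_boot`.
#' @export
cv_regression <- function(observed_cvs, predicted_cvs, n_boot = 1999,
                          seed = NULL) {
  ok <- is.finite(observed_cvs) & is.finite(predicted_cvs) &
    observed_cvs > 0 & predicted_cvs > 0
  ly <- log(observed_cvs[ok])
  lx <- log(predicted_cvs[ok])
  if (length(lx) < 3) stop("need at least 3 usable CV pairs", call. = FALSE)
  ma <- function(x, y) {
    S <- stats::cov(cbind(x, y))
    e <- eigen(S, symmetric = TRUE)
    v <- e$vectors[, 1]
    slope <- v[2] / v[1]
    c(slope = slope, intercept = mean(y) - slope * mean(x))
  }
  est <- ma(lx, ly)
  r2 <- stats::cor(lx, ly)^2
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ii <- sample.int(length(lx), replace = TRUE)
      if (stats::var(lx[ii]) == 0 || stats::var(ly[ii]) == 0)
        return(c(NA_real_, NA_real_))
      ma(lx[ii], ly[ii])
    }, numeric(2))
  })
  list(r2 = r2, slope = unname(est[1]), intercept = unname(est[2]),
       slope_ci = unname(stats::quantile(boot[1, ], c(0.025, 0.975),
                                         na.rm = TRUE)),
       intercept_ci = unname(stats::quantile(boot[2, ], c(0.025, 0.975),
                                             na.rm = TRUE)),
       n = length(lx), n_boot = n_boot)
}

#' Leaf-shuffle empirical null for CVs
#'
#' Permutes the leaf damage values of one survey among its plants
#' (preserving each plant's leaf count), breaking plant identity while
#' keeping the survey-level multiset of leaf values.  Plant damage is
#' recomputed as the mean of the assigned leaves; each permutation yields
#' the among-plant CV of plant means and the per-plant among-leaf CVs.
#'
#' @param survey A survey table (see [generate_survey()]) restricted to a
#'   single survey, with >= 2 plants.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @return A list: `among_plant` (CV of plant means per permutation),
#'   `among_leaf` (`n_perm` x n-plants matrix of within-plant CVs),
#'   `observed_among_plant` and `observed_among_leaf` for reference.
#' @export
shuffle_null <- function(survey, n_perm = 999, seed = NULL) {
  stopifnot(all(c("plant_id", "prop_damage") %in% names(survey)))
  if ("survey_id" %in% names(survey) &&
      length(unique(survey$survey_id)) > 1)
    stop("shuffle_null operates on a single survey", call. = FALSE)
  plant <- factor(survey$plant_id)
  if (nlevels(plant) < 2) stop("need at least 2 plants", call. = FALSE)
  vals <- survey$prop_damage
  obs_means <- tapply(vals, plant, mean)
  obs_leaf_cv <- tapply(vals, plant, sample_cv)
  with_seed(seed, {
    among_plant <- numeric(n_perm)
    among_leaf <- matrix(NA_real_, n_perm, nlevels(plant),
                         dimnames = list(NULL, levels(plant)))
    for (i in seq_len(n_perm)) {
      v <- sample(vals)
      pm <- tapply(v, plant, mean)
      among_plant[i] <- if (mean(pm) > 0) stats::sd(pm) / mean(pm) else NA_real_
      among_leaf[i, ] <- tapply(v, plant, sample_cv)
    }
    list(among_plant = among_plant, among_leaf = among_leaf,
         observed_among_plant = if (mean(obs_means) > 0)
           stats::sd(obs_means) / mean(obs_means) else NA_real_,
         observed_among_leaf = as.numeric(obs_leaf_cv))
  })
}

# bin a damage sample on the shared partition {0} U (0, w] U ... U (1-w, 1]
.damage_bin_props <- function(x, bin_width) {
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  pos <- x[x > 0]
  counts <- c(sum(x == 0),
              tabulate(findInterval(pos, breaks, left.open = TRUE,
                                    rightmost.closed = TRUE),
                       nbins = length(breaks) - 1))
  counts / length(x)
}

#' Bootstrapped Kullback-Leibler divergence from the neutral prediction
#'
#' Per bootstrap, a predicted sample of the observed size is simulated from
#' the fitted model; observed and predicted samples are binned on a shared
#' partition of an atom at exactly 0 plus damage classes of width
#' `bin_width`; `eps` is added to every cell and the cells renormalized;
#' KL(observed || predicted) is computed in nats and averaged across
#' bootstraps.
#'
#' @param observed Numeric vector of proportions.
#' @param fit A [fit_neutral()] result.
#' @param bin_width Damage-class width (default 0.05).
#' @param n_boot Number of bootstraps (default 100).
#' @param eps Regularizing constant added to each cell.
#' @param resample_observed If `TRUE`, also resample the observed sample
#'   (with replacement) in each bootstrap.
#' @param seed Optional integer seed.
#' @return Mean KL divergence (nats, >= 0), with the per-bootstrap values
#'   as attribute `"boots"`.
#' @export
kl_divergence <- function(observed, fit, bin_width = 0.05, n_boot = 100,
                          eps = 1e-10, resample_observed = FALSE,
                          seed = NULL) {
  stopifnot(length(observed) >= 1, inherits(fit, "neutral_fit"))
  model <- neutral_model(fit$lam_hat, fit$event)
  n <- length(observed)
  p_obs_base <- .damage_bin_props(observed, bin_width)
  with_seed(seed, {
    kls <- vapply(seq_len(n_boot), function(b) {
      p <- if (resample_observed)
        .damage_bin_props(sample(observed, n, replace = TRUE), bin_width)
      else p_obs_base
      q <- .damage_bin_props(simulate_damage(model, n), bin_width)
      p <- (p + eps) / sum(p + eps)
      q <- (q + eps) / sum(q + eps)
      sum(p * log(p / q))
    }, numeric(1))
    structure(mean(kls), boots = kls)
  })
}

#' Per-dataset comparison report
#'
#' Runs the full battery of observed-versus-predicted diagnostics for one
#' damage dataset: the neutral fit, Monte-Carlo-averaged KS comparison,
#' observed and mean-predicted probe vectors, the observed / predicted /
#' shuffled CV triplet, bootstrapped KL divergence, and AICc differences
#' against the HTLN and ZOIB competitors.
#'
#' @param values Numeric vector of proportions (one dataset: the leaves of
#'   a plant, or the plant means of a survey).
#' @param event An [event_params()] object (already rescaled for the plant
#'   scale if applicable).
#' @param precision Censoring band width shared by all three models.
#' @param n_rep Predicted replicates for KS and probes (default 100).
#' @param n_boot KL bootstraps (default 100).
#' @param cv_shuffled Optional shuffled CV for the triplet (e.g. the mean
#'   of a [shuffle_null()] distribution); `NA` if not applicable.
#' @param seed Integer seed; every stochastic step derives from it.
#' @return An object of class `"comparison_report"` (a list; serializable
#'   with [jsonlite::toJSON]).
#' @export
comparison_report <- function(values, event = event_params(),
                              precision = 0.005, n_rep = 100, n_boot = 100,
                              cv_shuffled = NA_real_, seed = 1) {
  fit <- fit_neutral(values, event, precision)
  ks <- ks_compare(values, fit, n_rep = n_rep, seed = seed)
  model <- neutral_model(fit$lam_hat, fit$event)
  pred <- with_seed(seed + 1, {
    sims <- replicate(n_rep, simulate_damage(model, length(values)),
                      simplify = FALSE)
    pm <- vapply(sims, function(s) as.numeric(probes(s)), numeric(10))
    cvs <- vapply(sims, sample_cv, numeric(1))
    list(probes = rowMeans(pm, na.rm = TRUE),
         cv = mean(cvs, na.rm = TRUE))
  })
  probe_obs <- probes(values)
  names(pred$probes) <- names(probe_obs)
  kl <- kl_divergence(values, fit, n_boot = n_boot, seed = seed + 2)
  htln <- fit_htln(values, precision)
  zoib <- fit_zoib(values, precision)
  structure(list(
    n = length(values),
    fit = fit,
    ks_stat = ks$ks_stat, ks_p = ks$ks_p, frac_signif = ks$frac_signif,
    probes_observed = as.numeric(probe_obs),
    probes_predicted = pred$probes,
    probe_names = names(probe_obs),
    cv_observed = sample_cv(values),
    cv_predicted = pred$cv,
    cv_shuffled = cv_shuffled,
    kl_divergence = as.numeric(kl),
    delta_aicc_htln = delta_aicc(htln, fit),
    delta_aicc_zoib = delta_aicc(zoib, fit),
    n_rep = n_rep, n_boot = n_boot, seed = seed),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Comparison report (n = %d, lambda-hat = %.4g)\n", x$n,
              x$fit$lam_hat))
  cat(sprintf("  KS: stat %.3f, p %.3f (%.0f%% of %d replicates p < 0.05)\n",
              x$ks_stat, x$ks_p, 100 * x$frac_signif, x$n_rep))
  cat(sprintf("  CV: observed %.3f, predicted %.3f, shuffled %s\n",
              x$cv_observed, x$cv_predicted,
              ifelse(is.na(x$cv_shuffled), "-",
                     sprintf("%.3f", x$cv_shuffled))))
  cat(sprintf("  KL divergence: %.4f nats\n", x$kl_divergence))
  cat(sprintf("  dAICc (HTLN: neutral) %.2f, (ZOIB: neutral) %.2f\n",
              x$delta_aicc_htln, x$delta_aicc_zoib))
  invisible(x)
}
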