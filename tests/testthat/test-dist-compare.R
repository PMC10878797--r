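test_that("Monte-Carlo KS comparison is self-consistent and detects gross misfit", {
  ep <- default_event()
  # data tested against their own generating model: typically compatible
  ok <- vapply(1:5, function(r) {
    x <- rounded_neutral_sample(2, 200, seed = 400 + r)
    f <- fit_neutral(x, ep)
    ks_compare(x, f, n_rep = 30, seed = r)$ks_p > 0.05
  }, logical(1))
  expect_gte(sum(ok), 4)

  # all-ones data against a near-zero attack rate: huge distance
  fake <- structure(list(lam_hat = 0.1, event = ep), class = "neutral_fit")
  ks <- ks_compare(rep(1, 50), fake, n_rep = 20, seed = 1)
  expect_gt(ks$ks_stat, 0.8)

  # identical samples give a zero two-sample statistic
  x <- rounded_neutral_sample(2, 100, seed = 409)
  expect_equal(unname(suppressWarnings(ks.test(x, x))$statistic), 0)
})

test_that("probes report the ten shape statistics in fixed order", {
  p <- probes(c(0, 0, 0, 1))
  expect_named(p, c("mean", "variance", "skew", "kurtosis", "minimum",
                    "maximum", "q25", "q50", "q75", "gini"))
  expect_equal(p[["mean"]], 0.25)
  expect_equal(p[["q50"]], 0)
  expect_equal(p[["maximum"]], 1)
  expect_true(p[["q25"]] <= p[["q50"]] && p[["q50"]] <= p[["q75"]])

  set.seed(42)
  z <- rnorm(1e5, 5, 1)
  pz <- probes(z)
  expect_equal(pz[["kurtosis"]], 3, tolerance = 0.1 / 3)
  expect_equal(pz[["skew"]], 0, tolerance = 0.05)

  pc <- probes(rep(0.2, 5))
  expect_equal(pc[["variance"]], 0)
  expect_true(attr(pc, "degenerate"))
})

test_that("constrained variance partition equals brute-force sums of squares", {
  # 4 rows, 2 probes, worked by direct enumeration
  X <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3), ncol = 2)
  g <- c("obs", "obs", "pred", "pred")
  Z <- scale(X)
  grand <- colMeans(Z)
  ss_tot <- sum(sweep(Z, 2, grand)^2)
  ss_b <- 2 * sum((colMeans(Z[1:2, ]) - grand)^2) +
    2 * sum((colMeans(Z[3:4, ]) - grand)^2)
  res <- probe_variance_partition(X, g, n_perm = 0)
  expect_equal(res$r2, ss_b / ss_tot, tolerance = 1e-12)

  # identical rows in both groups: nothing to explain
  Xi <- rbind(c(1, 2), c(3, 1), c(1, 2), c(3, 1))
  expect_equal(probe_variance_partition(Xi, g, n_perm = 0)$r2, 0,
               tolerance = 1e-12)
})

test_that("randomly labelled probes sit inside their permutation null", {
  set.seed(43)
  X <- matrix(rnorm(40 * 6), 40, 6)
  g <- sample(rep(c("obs", "pred"), 20))
  res <- probe_variance_partition(X, g, n_perm = 499, seed = 44)
  expect_gt(res$p_value, 0.05)
  expect_lt(res$r2, quantile(res$perm, 0.95))
})

test_that("zero-variance probe columns are dropped with a warning", {
  X <- cbind(rnorm(10), rep(1, 10))
  colnames(X) <- c("a", "b")
  expect_warning(res <- probe_variance_partition(X, rep(c("o", "p"), 5),
                                                 n_perm = 0),
                 "zero-variance")
  expect_equal(res$dropped, "b")
})

test_that("constrained R2 agrees with an RDA fit", {
  skip_if_not_installed("vegan")
  set.seed(45)
  X <- matrix(rnorm(30 * 10), 30, 10)
  X[1:15, 1] <- X[1:15, 1] + 1  # group signal in one probe
  g <- rep(c("observed", "predicted"), each = 15)
  mine <- probe_variance_partition(X, g, n_perm = 0)$r2
  rda_fit <- vegan::rda(scale(X) ~ g)
  expect_equal(mine, rda_fit$CCA$tot.chi / rda_fit$tot.chi,
               tolerance = 1e-10)
})

test_that("major-axis regression matches geometric oracles", {
  cv <- exp(seq(-1, 1, length.out = 10))
  r <- cv_regression(cv, cv, n_boot = 50, seed = 46)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)

  r2x <- cv_regression(2 * cv, cv, n_boot = 50, seed = 46)
  expect_equal(r2x$slope, 1, tolerance = 1e-12)
  expect_equal(r2x$intercept, log(2), tolerance = 1e-12)

  # anisotropic Gaussian cloud: slope from minimizing total perpendicular
  # distance over rotation angle (independent numerical oracle)
  set.seed(47)
  lx <- rnorm(200, 0, 1.5)
  ly <- 0.7 * lx + rnorm(200, 0, 0.5)
  fit <- cv_regression(exp(ly), exp(lx), n_boot = 50, seed = 48)
  perp <- function(theta) {
    ux <- cos(theta); uy <- sin(theta)
    dx <- lx - mean(lx); dy <- ly - mean(ly)
    sum((dx^2 + dy^2) - (dx * ux + dy * uy)^2)
  }
  th <- optimize(perp, c(-pi / 2 + 1e-6, pi / 2 - 1e-6))$minimum
  expect_equal(fit$slope, tan(th), tolerance = 1e-6)
  expect_true(fit$slope_ci[1] <= fit$slope && fit$slope <= fit$slope_ci[2])
})

test_that("cv regression drops unusable pairs and needs three of them", {
  expect_error(cv_regression(c(1, 2), c(1, 2)), "3 usable")
  r <- cv_regression(c(1, 2, 3, 0, NA), c(1, 2, 3, 1, 1), n_boot = 20,
                     seed = 1)
  expect_equal(r$n, 3)
})

test_that("leaf shuffling preserves the survey multiset and detects heterogeneity", {
  tab <- generate_survey(synth_config(seed = 50))
  sn <- shuffle_null(tab, n_perm = 50, seed = 51)
  expect_length(sn$among_plant, 50)
  expect_identical(sn, shuffle_null(tab, n_perm = 50, seed = 51))
  # equal leaf counts: the mean of shuffled plant means is the grand mean,
  # so the permutation can move the CV but never the centre
  expect_equal(sn$observed_among_plant,
               sd(tapply(tab$prop_damage, tab$plant_id, mean)) /
                 mean(tab$prop_damage), tolerance = 1e-12)

  # identical damage everywhere: shuffled CV is exactly zero
  flat <- tab
  flat$prop_damage <- 0.25
  snf <- shuffle_null(flat, n_perm = 20, seed = 52)
  expect_true(all(snf$among_plant == 0))

  # injected plant-level heterogeneity: observed among-plant CV extreme
  het <- generate_survey(synth_config(plant_sigma = 1, seed = 53))
  snh <- shuffle_null(het, n_perm = 199, seed = 54)
  expect_gt(snh$observed_among_plant,
            quantile(snh$among_plant, 0.975, na.rm = TRUE))

  expect_error(shuffle_null(tab[tab$plant_id == 1, ]), "2 plants")
})

test_that("KL divergence is non-negative and increases with misfit", {
  ep <- default_event()
  x <- rounded_neutral_sample(3, 500, seed = 60)
  f <- fit_neutral(x, ep)
  kl_fit <- kl_divergence(x, f, n_boot = 30, seed = 61)
  expect_gte(min(attr(kl_fit, "boots")), 0)
  wrong <- structure(list(lam_hat = f$lam_hat * 10, event = ep),
                     class = "neutral_fit")
  kl_wrong <- kl_divergence(x, wrong, n_boot = 30, seed = 61)
  expect_lt(as.numeric(kl_fit), as.numeric(kl_wrong))
})

test_that("binning partitions the unit interval with a zero atom", {
  pr <- neutralherb:::.damage_bin_props(c(0, 0, 0.001, 0.05, 0.051, 1), 0.05)
  expect_equal(sum(pr), 1)
  expect_equal(pr[1], 2 / 6)    # exact zeros
  expect_equal(pr[2], 2 / 6)    # (0, 0.05]
  expect_equal(pr[3], 1 / 6)    # (0.05, 0.10]
  expect_equal(pr[21], 1 / 6)   # (0.95, 1]
})

test_that("comparison reports are deterministic given a seed", {
  x <- rounded_neutral_sample(2, 120, seed = 70)
  r1 <- comparison_report(x, n_rep = 15, n_boot = 15, seed = 71)
  r2 <- comparison_report(x, n_rep = 15, n_boot = 15, seed = 71)
  expect_identical(r1, r2)
  expect_true(r1$ks_stat >= 0 && r1$ks_stat <= 1)
  expect_gte(r1$kl_divergence, 0)
  expect_length(r1$probes_predicted, 10)
})
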