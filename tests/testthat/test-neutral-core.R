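test_that("simulator honours the Poisson event count structure", {
  ep <- default_event()
  expect_true(all(simulate_damage(neutral_model(0, ep), 100, seed = 1) == 0))

  x <- simulate_damage(neutral_model(2, ep), 1e5, seed = 2)
  p0 <- exp(-2)
  se <- sqrt(p0 * (1 - p0) / 1e5)
  expect_lt(abs(mean(x == 0) - p0), 3 * se)

  # with tiny event bounds truncation at 1 is negligible and the compound
  # Poisson mean identity E[damage] = lam * E[phi] holds
  epn <- narrow_event()
  lam <- 2
  y <- simulate_damage(neutral_model(lam, epn), 1e5, seed = 3)
  mu <- lam * event_moment(1, epn)
  se_mu <- sqrt(lam * event_moment(2, epn) / 1e5)
  expect_lt(abs(mean(y) - mu), 3 * se_mu)
})

test_that("mixed distribution conserves mass with an exact zero atom", {
  for (ep in list(default_event(), plant_scale_event_params(default_event(), 10))) {
    for (lam in c(0.01, 0.1, 1, 10, 100)) {
      d <- damage_distribution(neutral_model(lam, ep))
      expect_identical(d$p0, exp(-lam))
      expect_equal(d$p0 + d$p1 + trapz_density(d), 1, tolerance = 1e-6)
      expect_true(all(d$density >= 0) && d$p1 >= 0)
    }
  }
})

test_that("numerical density agrees with the simulator", {
  ep <- default_event()
  for (lam in c(0.5, 5, 50)) {
    m <- neutral_model(lam, ep)
    d <- damage_distribution(m)
    x <- simulate_damage(m, 1e5, seed = 100 + lam)
    expect_lt(ks_distance(x, d), 0.01)
  }
})

test_that("a large attack rate saturates the atom at full consumption", {
  d <- damage_distribution(neutral_model(500, default_event()))
  expect_gte(d$p1, 0.99)
})

test_that("mean rises and CV falls monotonically with the attack rate", {
  ep <- default_event()
  lams <- c(0.1, 1, 10, 100)
  ds <- lapply(lams, function(l) damage_distribution(neutral_model(l, ep)))
  means <- vapply(ds, distribution_mean, numeric(1))
  cvs <- vapply(ds, distribution_cv, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(diff(cvs) < 0))
})

test_that("likelihood handles atoms exactly and covers simulated data", {
  ep <- default_event()
  m <- neutral_model(1, ep)
  expect_equal(loglik_neutral(rep(0, 25), m), -25)
  x <- simulate_damage(neutral_model(3, ep), 200, seed = 5)
  expect_true(is.finite(loglik_neutral(x, neutral_model(3, ep))))
  expect_error(loglik_neutral(c(-0.1, 0.5), m), "0, 1")
})

test_that("interval-censored loglik converges to the density form", {
  # on interior continuous data, censored loglik ~ density loglik +
  # n log(precision), with error shrinking quadratically in the band width
  ep <- event_params(0.02, 0.8)
  m <- neutral_model(4, ep)
  x <- simulate_damage(m, 300, seed = 6)
  x <- x[x > 0.05 & x < 0.9]
  d <- damage_distribution(m)
  ld <- loglik_neutral(x, m, mode = "density", dist = d)
  err <- vapply(c(1e-2, 1e-3), function(prec) {
    li <- loglik_neutral(x, m, precision = prec, dist = d)
    abs(li - (ld + length(x) * log(prec)))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.05)
})

test_that("attack-rate MLE recovers the generating rate", {
  ep <- default_event()
  errs <- vapply(1:5, function(r) {
    x <- rounded_neutral_sample(2, 500, seed = 600 + r)
    f <- fit_neutral(x, ep)
    abs(f$lam_hat - 2) / 2
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("fit metadata is coherent and degenerate data are flagged", {
  x <- rounded_neutral_sample(2, 200, seed = 11)
  f <- fit_neutral(x)
  expect_s3_class(f, "neutral_fit")
  expect_equal(f$aicc, -2 * f$loglik + 2 + 4 / (f$n - 2))
  expect_length(f$flags, 0)

  f0 <- fit_neutral(rep(0, 40))
  expect_lte(f0$lam_hat, 1e-3)
  expect_true("degenerate" %in% f0$flags)
})

test_that("interval and density modes agree on continuous interior data", {
  ep <- default_event()
  x <- simulate_damage(neutral_model(3, ep), 400, seed = 12)
  fi <- fit_neutral(x, ep, mode = "interval")
  fd <- fit_neutral(x, ep, mode = "density")
  expect_lt(abs(fi$lam_hat - fd$lam_hat) / fd$lam_hat, 0.05)
})

test_that("presence/absence closed form matches its derivation", {
  expect_equal(fit_presence_absence(0, 30)$lam_hat, 0)
  expect_equal(fit_presence_absence(15, 30)$lam_hat, log(2))
  f <- fit_presence_absence(30, 30)
  expect_true(is.infinite(f$lam_hat) && "at_upper_bound" %in% f$flags)

  # recovery: binary-thresholded neutral data at lam = 1
  x <- simulate_damage(neutral_model(1, default_event()), 2000, seed = 13)
  nd <- sum(x > 0)
  fpa <- fit_presence_absence(nd, length(x))
  p <- 1 - exp(-1)
  se_lam <- sqrt(p * (1 - p) / 2000) / (1 - p)  # delta method
  expect_lt(abs(fpa$lam_hat - 1), 3 * se_lam)
})

test_that("plant-scale rescaling divides both bounds by L", {
  ep <- default_event()
  expect_equal(plant_scale_event_params(ep, 1), ep)
  ep10 <- plant_scale_event_params(ep, 10)
  expect_equal(ep10$phi_m, 0.0005)
  expect_equal(ep10$phi_M, 0.1)
  expect_equal(ep10$alpha, ep$alpha)
})
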