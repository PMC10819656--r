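test_that("the delayed-exponential model evaluates to its analytic values", {
  p <- kinetics_params(6.8, 42, 4.3, 14.2)
  # Heaviside off before the time delay
  expect_equal(model_value(c(0, 2, 4.29), p), rep(6.8, 3))
  # one time constant past the delay: a0 + (1 - 1/e) * ap
  expect_equal(model_value(4.3 + 14.2, p), 6.8 + (1 - exp(-1)) * 42)

  # off-transient asymptote: a0 - ap - asc
  off <- kinetics_params(50, 40, 5, 10, asc = 5, tdsc = 20, tau_sc = 15,
                         direction = "off")
  expect_equal(model_value(1e6, off), 5, tolerance = 1e-12)

  # continuity at both time delays
  eps <- 1e-9
  expect_equal(model_value(p$tdp - eps, p), model_value(p$tdp, p),
               tolerance = 1e-6)
  expect_equal(model_value(off$tdsc - eps, off), model_value(off$tdsc, off),
               tolerance = 1e-6)

  expect_error(kinetics_params(6.8, 42, 4.3, -1), "tau_p")
  expect_error(kinetics_params(6.8, 42, 4.3, 14, asc = 5, tdsc = 2, tau_sc = 10),
               "tdsc")
})

test_that("noiseless transients are recovered to high precision", {
  true <- c(a0 = 6.8, ap = 42, tdp = 4.3, tau_p = 14.2)
  d <- simulate_transient(kinetics_params(6.8, 42, 4.3, 14.2), 117, dt = 1)
  fit <- fit_vo2_kinetics(d$t, d$vo2, "mono", "on")
  expect_true(fit$converged)
  expect_rel_equal(fit$coef, true, 1e-4)

  # off-transient, fitted through the breath-series interface
  off <- kinetics_params(48.8, 40, 8, 35, direction = "off")
  marks <- phase_marks(0, 10, 20, 320)
  tr <- seq(0, 299, by = 1)
  s <- breath_series(
    tibble::tibble(time = c(5, 12, 15, 18, 20 + tr),
                   vo2 = c(544, 3900, 3902, 3904, model_value(tr, off) * 80)),
    marks, 80
  )
  rfit <- fit_transient(s, "recovery", "mono", exclude = 0)
  expect_rel_equal(rfit$coef, c(a0 = 48.8, ap = 40, tdp = 8, tau_p = 35), 1e-3)
})

test_that("the bi-exponential model nests the mono-exponential", {
  # noiseless mono-generated data: the second amplitude vanishes and the
  # two fitted curves coincide
  d0 <- simulate_transient(kinetics_params(6.8, 42, 4.3, 14.2), 117, dt = 1)
  mono0 <- fit_vo2_kinetics(d0$t, d0$vo2, "mono", "on")
  bi0 <- fit_vo2_kinetics(d0$t, d0$vo2, "bi", "on")
  expect_lt(bi0$params$asc, 1e-3 * bi0$params$ap)
  tg <- seq(0, 117, by = 1)
  expect_lt(max(abs(model_value(tg, bi0$params) - model_value(tg, mono0$params))),
            1e-3)

  # under noise the richer model can only reduce the residual sum of squares
  d <- simulate_transient(kinetics_params(6.8, 42, 4.3, 14.2), 117, dt = 1,
                          noise_sd = 1, seed = 77)
  mono <- fit_vo2_kinetics(d$t, d$vo2, "mono", "on")
  bi <- fit_vo2_kinetics(d$t, d$vo2, "bi", "on")
  expect_lte(bi$rss, mono$rss + 1e-9)
})

test_that("parameters are recovered with small median bias under breath noise", {
  true <- c(a0 = 6.8, ap = 42, tdp = 4.3, tau_p = 14.2)
  p <- kinetics_params(6.8, 42, 4.3, 14.2)
  est <- t(vapply(1:50, function(i) {
    d <- simulate_transient(p, 117, dt = 1, noise_sd = 2, seed = 400 + i)
    fit_vo2_kinetics(d$t, d$vo2, "mono", "on")$coef
  }, numeric(4)))
  bias <- apply(sweep(est, 2, true) / rep(true, each = 50), 2, median)
  expect_true(all(abs(bias) < 0.05))
})

test_that("fits are deterministic given identical input", {
  d <- simulate_transient(kinetics_params(6.8, 42, 4.3, 14.2), 117, dt = 1,
                          noise_sd = 2, seed = 9)
  f1 <- fit_vo2_kinetics(d$t, d$vo2, "mono", "on")
  f2 <- fit_vo2_kinetics(d$t, d$vo2, "mono", "on")
  expect_identical(f1$coef, f2$coef)
})

test_that("residual bootstrap collapses on noiseless data and is reproducible", {
  d <- simulate_transient(kinetics_params(6.8, 42, 4.3, 14.2), 117, dt = 1)
  fit <- fit_vo2_kinetics(d$t, d$vo2, "mono", "on")
  bs <- bootstrap_fit(fit, b = 30, seed = 1)
  expect_equal(nrow(bs$bootstrap), 30)
  expect_lt(max(bs$ci95[, "upper"] - bs$ci95[, "lower"]), 1e-5)

  # CI brackets the point estimate; fixed seed reproduces bit-identically
  dn <- simulate_transient(kinetics_params(6.8, 42, 4.3, 14.2), 117, dt = 1,
                           noise_sd = 2, seed = 4)
  fn <- fit_vo2_kinetics(dn$t, dn$vo2, "mono", "on")
  b1 <- bootstrap_fit(fn, b = 50, seed = 123)
  b2 <- bootstrap_fit(fn, b = 50, seed = 123)
  expect_identical(b1$ci95, b2$ci95)
  expect_identical(b1$bootstrap, b2$bootstrap)
  for (nm in names(fn$coef)) {
    expect_lte(b1$ci95[nm, "lower"], fn$coef[[nm]] + 1e-9)
    expect_gte(b1$ci95[nm, "upper"], fn$coef[[nm]] - 1e-9)
  }
})

test_that("accumulated VO2 integrates net uptake over the exercise phase", {
  # constant net rate of 4.2 L/min above a 0.6 L/min baseline for 117 s
  marks <- phase_marks(0, 10, 127, 140)
  te <- 10 + c(seq(0, 116.75, by = 0.25), 116.999)
  s <- breath_series(tibble::tibble(time = te, vo2 = rep(4800, length(te))),
                     marks, 80)
  acc <- accumulated_vo2(s, baseline_rate = 0.6)
  expect_equal(acc$net_volume_l, 4.2 * 117 / 60, tolerance = 1e-3)
  expect_equal(acc$mean_net_rate_l_min, 4.2, tolerance = 1e-3)

  # VO2 identically at baseline integrates to zero
  s0 <- breath_series(tibble::tibble(time = te, vo2 = rep(600, length(te))),
                      marks, 80)
  acc0 <- accumulated_vo2(s0, baseline_rate = 0.6)
  expect_equal(acc0$net_volume_l, 0)
  expect_equal(acc0$mean_net_rate_l_min, 0)

  expect_error(accumulated_vo2(s, baseline_rate = 0), "positive")
})

test_that("trapezoidal integrals match the closed-form antiderivative", {
  mass <- 87.9
  p <- kinetics_params(6.8, 42, 4.3, 14.2)
  s <- transient_series(p, mass = mass, dt = 1)
  base_rate <- p$a0 * mass / 1000
  acc <- accumulated_vo2(s, base_rate)
  closed <- net_on_integral_rel(p, 116) * mass / 1000 / 60 # integral to last breath
  expect_lt(abs(acc$net_volume_l - closed) / closed, 0.001)

  # off-transient EPOC against its closed form
  off <- kinetics_params(48.8, 42, 0, 30, direction = "off")
  marks <- phase_marks(0, 5, 10, 400)
  tr <- seq(0, 299, by = 1)
  sr <- breath_series(
    tibble::tibble(time = c(2, 6, 8, 10 + tr),
                   vo2 = c(598, 4200, 4210, model_value(tr, off) * mass)),
    marks, mass
  )
  got <- epoc(sr, baseline_rate = 6.8 * mass / 1000, window_s = 300)
  # net rel = (48.8 - 6.8) - 42*(1 - e^(-t/30)) = 42 e^(-t/30)
  closed_off <- 42 * 30 * (1 - exp(-299 / 30)) * mass / 1000 / 60
  expect_lt(abs(got - closed_off) / closed_off, 0.001)
})

test_that("EPOC is zero at baseline and non-decreasing in window length", {
  marks <- phase_marks(0, 5, 10, 400)
  tr <- seq(10, 399, by = 1)
  s <- breath_series(
    tibble::tibble(time = c(2, 6, tr), vo2 = rep(600, length(tr) + 2)),
    marks, 80
  )
  expect_equal(epoc(s, baseline_rate = 0.6, window_s = 300), 0)

  gen <- generate_cohort(cohort_spec(n = 1, master_seed = 8))[[1]]
  br <- phase_mean_rate(gen$series, "baseline")
  e1 <- epoc(gen$series, br, window_s = 120)
  e2 <- epoc(gen$series, br, window_s = 300)
  e3 <- epoc(gen$series, br, window_s = 420)
  expect_lte(e1, e2)
  expect_lte(e2, e3)
})
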