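test_that("artifact-flagged breaths are removed exactly and counted", {
  marks <- phase_marks(0, 300, 310, 320)
  rec <- tibble::tibble(time = 1:100, vo2 = rep(500, 100),
                        artifact = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE),
                                       each = 20)[1:100])
  rec$artifact <- FALSE
  rec$artifact[c(10, 30, 55, 80)] <- TRUE
  s <- breath_series(rec, marks, 80)

  res <- drop_flagged(s)
  expect_equal(n_breaths(res$series), 96)
  expect_equal(res$report$n_artifact_removed, 4)
  expect_equal(res$report$n_input,
               res$report$n_artifact_removed + res$report$n_retained)
  expect_false(any(res$series$records$artifact))

  # no flags: identity
  s0 <- flat_series(1:10, rep(400, 10))
  res0 <- drop_flagged(s0)
  expect_equal(res0$series$records, s0$records)
  expect_equal(res0$report$n_artifact_removed, 0)

  # simulator-injected artifacts are recovered exactly
  gen <- generate_cohort(cohort_spec(n = 1, master_seed = 5))[[1]]$series
  injected <- gen$records$time[gen$records$artifact]
  kept <- drop_flagged(gen)$series$records$time
  expect_setequal(setdiff(gen$records$time, kept), injected)
})

test_that("the SD retention band removes outliers found by brute force", {
  # constant series: SD = 0 is degenerate, nothing removed
  s_const <- flat_series(1:50, rep(500, 50))
  expect_equal(sd3_filter(s_const)$report$n_sd_removed, 0)
  expect_equal(sd3_filter(s_const)$series$records, s_const$records)

  # 100 constant breaths plus one spike: exactly the spike removed,
  # membership checked against mean/SD recomputed by brute force
  vo2 <- c(rep(500, 100), 5000)
  s <- flat_series(1:101, vo2)
  res <- sd3_filter(s, k = 3)
  mu <- mean(vo2); sdev <- sd(vo2)
  keep_oracle <- vo2 >= mu - 3 * sdev & vo2 <= mu + 3 * sdev
  expect_equal(res$series$records$vo2, vo2[keep_oracle])
  expect_equal(res$report$n_sd_removed, 1)
  expect_false(5000 %in% res$series$records$vo2)

  # survivors are a subset of the input; refiltering removes no more than
  # the first pass did
  set.seed(42)
  noisy <- flat_series(1:200, 500 + rnorm(200, 0, 50))
  p1 <- sd3_filter(noisy, k = 2)
  p2 <- sd3_filter(p1$series, k = 2)
  expect_true(all(p1$series$records$time %in% noisy$records$time))
  expect_lte(p2$report$n_sd_removed, p1$report$n_sd_removed)
})

test_that("per-phase scope computes its bands per phase", {
  marks <- phase_marks(0, 50, 100, 150)
  set.seed(9)
  rec <- tibble::tibble(
    time = c(1:49, 51:99, 101:149),
    vo2 = c(rnorm(49, 500, 10), rnorm(49, 4000, 10), rnorm(49, 1000, 10))
  )
  rec$vo2[25] <- 900 # outlier within baseline, unremarkable session-wide
  s <- breath_series(rec, marks, 80)
  by_phase <- sd3_filter(s, scope = "phase")
  whole <- sd3_filter(s, scope = "session")
  expect_false(900 %in% by_phase$series$records$vo2)
  expect_true(900 %in% whole$series$records$vo2)
})

test_that("centred moving average matches hand computation and keeps length", {
  s <- flat_series(c(1, 2, 3), c(0, 3, 6))
  sm <- moving_average(s, 3)
  expect_equal(sm$records$vo2, c(1.5, 3, 4.5))
  expect_equal(sm$records$time, s$records$time)

  s_const <- flat_series(1:20, rep(700, 20))
  expect_equal(moving_average(s_const, 3)$records$vo2, rep(700, 20))

  set.seed(1)
  s_rand <- flat_series(1:57, 500 + rnorm(57, 0, 30))
  expect_equal(n_breaths(moving_average(s_rand, 5)), 57)
})

test_that("temporal binning emits per-bin means at bin midpoints", {
  marks <- phase_marks(0, 25, 30, 35)
  s <- breath_series(tibble::tibble(time = 1:20, vo2 = (1:20) * 10), marks, 80)
  b <- time_bin(s, 10)
  # members 1..9 and 10..19 in the first two bins
  expect_equal(b$records$time[1:2], c(5, 15))
  expect_equal(b$records$vo2[1:2], c(50, 145))

  one <- flat_series(3, 777)
  b1 <- time_bin(one, 10)
  expect_equal(n_breaths(b1), 1)
  expect_equal(b1$records$vo2, 777)

  # VO2*time mass conserved within quadrature error at uniform spacing,
  # compared over the common support of the two grids
  p <- kinetics_params(6.8, 42, 4.3, 14.2)
  tr <- transient_series(p, dt = 1)
  bb <- time_bin(tr, 10)
  ex_raw <- slice_phase(tr, "exercise", rezero = TRUE)$records
  ex_bin <- slice_phase(bb, "exercise", rezero = TRUE)$records
  lo <- min(ex_bin$time); hi <- max(ex_bin$time)
  inner <- ex_raw[ex_raw$time >= lo & ex_raw$time <= hi, ]
  m_raw <- pracma::trapz(inner$time, inner$vo2)
  m_bin <- pracma::trapz(ex_bin$time, ex_bin$vo2)
  expect_lt(abs(m_bin - m_raw) / m_raw, 0.01)
})

test_that("the full chain never adds breaths nor reorders time", {
  for (seed in 1:5) {
    gen <- generate_cohort(cohort_spec(n = 1, master_seed = 200 + seed))[[1]]$series
    out <- clean_breaths(gen)
    expect_lte(n_breaths(out$series), n_breaths(gen))
    expect_true(all(diff(out$series$records$time) > 0))
    expect_equal(out$report$n_input,
                 out$report$n_artifact_removed + out$report$n_sd_removed +
                   out$report$n_retained)
  }
})

test_that("the chain denoises without distorting the fitted kinetics curve", {
  # artifact-free, low-noise subjects: the curve implied by fitting the
  # cleaned series stays within a few percent (RMS, relative to the primary
  # amplitude) of the curve fitted to raw breaths
  for (seed in c(101, 104, 108)) {
    spec <- cohort_spec(n = 1, master_seed = seed, artifact_rate = 0,
                        params = list(vo2_sd = c(0.5, 0)))
    s <- generate_cohort(spec)[[1]]
    raw_fit <- fit_transient(s$series, "exercise", exclude = 0)
    cl_fit <- fit_transient(clean_breaths(s$series)$series, "exercise",
                            exclude = 0)
    tg <- seq(0, min(max(raw_fit$data$t), max(cl_fit$data$t)), by = 1)
    rms <- sqrt(mean((model_value(tg, raw_fit$params) -
                        model_value(tg, cl_fit$params))^2))
    expect_lt(rms / raw_fit$params$ap, 0.05)
  }
})
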