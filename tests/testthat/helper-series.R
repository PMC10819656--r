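# Small in-code fixtures shared across test files.

# a minimal series: breaths on a regular grid within one long baseline phase
flat_series <- function(times, vo2, mass = 80,
                        marks = phase_marks(0, max(times) + 5,
                                            max(times) + 6, max(times) + 7)) {
  breath_series(tibble::tibble(time = times, vo2 = vo2), marks, mass)
}

# a three-phase series whose exercise VO2 follows a delayed exponential
# (mass-normalised params), sampled at `dt` seconds in every phase
transient_series <- function(params_on, mass = 87.9, baseline_s = 60,
                             exercise_s = 117, recovery_s = 120, dt = 1,
                             recovery_level = NULL) {
  marks <- phase_marks(0, baseline_s, baseline_s + exercise_s,
                       baseline_s + exercise_s + recovery_s)
  tb <- seq(0, baseline_s - dt / 2, by = dt)
  te <- seq(0, exercise_s - dt / 2, by = dt)
  tr <- seq(0, recovery_s - dt / 2, by = dt)
  rel <- c(
    rep(params_on$a0, length(tb)),
    model_value(te, params_on),
    rep(if (is.null(recovery_level)) params_on$a0 else recovery_level, length(tr))
  )
  breath_series(
    tibble::tibble(time = c(tb, baseline_s + te, baseline_s + exercise_s + tr),
                   vo2 = rel * mass),
    marks, mass
  )
}

# closed-form integral of max(model - a0, 0) for an on-transient without
# slow component, over phase time [0, T], in (mL/kg/min)*s
net_on_integral_rel <- function(params, T) {
  if (T <= params$tdp) return(0)
  u <- T - params$tdp
  params$ap * (u - params$tau_p * (1 - exp(-u / params$tau_p)))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
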