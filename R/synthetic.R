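# Synthetic breath-by-breath data generator. The forward model is the same
# delayed-exponential kinetics the fitting module estimates, sampled on
# stochastic breath times with additive Gaussian noise and optional
# artifact spikes, so every pipeline stage has a ground-truth oracle.
#
# Default cohort parameters emulate a group of highly trained CrossFit
# athletes performing a ~117 s maximal barbell workout: body mass
# 87.9 +/- 10.5 kg, primary on-transient amplitude 42.0 +/- 6.0
# mL/kg/min, time delay 4.3 +/- 2.2 s, time constant 14.2 +/- 6.0 s,
# baseline VO2 0.6 +/- 0.1 L/min, lactate rising from 1.5 +/- 0.3 to a
# post-exercise peak of 20.7 +/- 2.6 mM, glucose 97.1 +/- 4.6 to
# 141.8 +/- 8.6 mg/dL, Borg RPE 6 +/- 1 to 18 +/- 2.

.default_cohort_params <- function() {
  list(
    mass = c(87.9, 10.5), # kg
    a0_rate = c(0.6, 0.1), # baseline VO2, L/min
    ap = c(42.0, 6.0), # mL/kg/min
    tdp = c(4.3, 2.2), # s
    tau_p = c(14.2, 6.0), # s
    duration_exercise = c(117, 10), # s
    tau_off = c(35, 8), # s, recovery primary time constant
    td_off = c(8, 3), # s
    lactate_baseline = c(1.5, 0.3), # mM
    lactate_peak = c(20.7, 2.6), # mM
    glucose_baseline = c(97.1, 4.6), # mg/dL
    glucose_post = c(141.8, 8.6), # mg/dL
    rpe_baseline = c(6, 1),
    rpe_post = c(18, 2),
    vo2_sd = c(2, 0) # breath noise, mL/kg/min
  )
}

#' Specification of a synthetic cohort
#'
#' Defines the generating distributions for a cohort of synthetic subjects.
#' Each parameter is drawn independently from a normal distribution
#' truncated to physiologically positive values; setting an SD to zero
#' pins that parameter at its mean.
#'
#' @param n Number of subjects (default 14).
#' @param master_seed Integer master seed; subject `i` derives its own seed
#'   deterministically from `(master_seed, i)`.
#' @param params Named list of `c(mean, sd)` pairs overriding the default
#'   cohort values (see Details of [make_subject()] for names).
#' @param baseline_s,recovery_s Modelled baseline and recovery durations in
#'   seconds (defaults 120 and 420; recovery covers the 7-min blood
#'   sampling window).
#' @param artifact_rate Per-breath probability of an injected artifact
#'   spike, in `[0, 0.1]` (default 0.02).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 14, master_seed = 1L, params = list(),
                        baseline_s = 120, recovery_s = 420,
                        artifact_rate = 0.02) {
  stopifnot(n >= 1, baseline_s > 0, recovery_s > 0)
  if (artifact_rate < 0 || artifact_rate > 0.1) {
    rlang::abort("artifact_rate must lie in [0, 0.1]")
  }
  p <- .default_cohort_params()
  for (nm in names(params)) {
    if (!nm %in% names(p)) rlang::abort(sprintf("unknown cohort parameter '%s'", nm))
    p[[nm]] <- params[[nm]]
  }
  if (any(vapply(p, function(v) v[2] < 0, logical(1)))) {
    rlang::abort("parameter SDs must be non-negative")
  }
  structure(
    list(n = as.integer(n), master_seed = as.integer(master_seed),
         params = p, baseline_s = baseline_s, recovery_s = recovery_s,
         artifact_rate = artifact_rate),
    class = "cohort_spec"
  )
}

# deterministic 32-bit sub-seed for subject index under a master seed
.subject_seed <- function(master_seed, index) {
  as.integer((as.double(master_seed) * 100003 + index * 7919) %% 2147483647)
}

# normal draw truncated below at `lower` (simple rejection; SD 0 returns mean)
.rtnorm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= lower)
  }
  out
}

#' Draw one synthetic subject profile
#'
#' Draws the subject's ground-truth generating parameters (body mass,
#' on/off kinetics, metabolic panel values, noise settings) from the
#' cohort spec's truncated normal distributions. Deterministic for a given
#' `(master_seed, index)` pair.
#'
#' The drawn on-transient is `kinetics_params(a0, ap, tdp, tau_p, "on")`
#' with `a0` the mass-normalised baseline rate. The off-transient decays
#' from the end-exercise VO2 back towards baseline with a slower primary
#' time constant plus a small long-tail second component, so recovery VO2
#' remains mildly elevated over the 5-min EPOC window, as observed after
#' maximal efforts.
#'
#' @param spec A [cohort_spec()].
#' @param index Subject index in `1:spec$n`.
#' @return An object of class `subject_profile`.
#' @export
make_subject <- function(spec, index) {
  stopifnot(inherits(spec, "cohort_spec"), index >= 1)
  seed <- .subject_seed(spec$master_seed, index)
  set.seed(seed)
  p <- spec$params
  draw <- function(nm, lower = 0) .rtnorm(1, p[[nm]][1], p[[nm]][2], lower)

  mass <- draw("mass", 40)
  a0_rate <- draw("a0_rate", 0.2) # L/min
  a0_rel <- a0_rate * 1000 / mass # mL/kg/min
  ap <- draw("ap", 5)
  tdp <- max(draw("tdp", -Inf), 0)
  tau_p <- draw("tau_p", 2)
  dur_ex <- draw("duration_exercise", 60)
  on <- kinetics_params(a0_rel, ap, tdp, tau_p, direction = "on")

  # end-exercise level; recovery decays from it back to baseline with a
  # fast primary component and a small slow tail (invented, see vignette)
  end_rel <- model_value(dur_ex, on)
  excess <- end_rel - a0_rel
  off <- kinetics_params(
    a0 = end_rel,
    ap = 0.85 * excess,
    tdp = max(draw("td_off", -Inf), 0),
    tau_p = draw("tau_off", 5),
    asc = 0.15 * excess, tdsc = 60, tau_sc = 300,
    direction = "off"
  )

  la_base <- draw("lactate_baseline", 0.3)
  la_peak <- max(draw("lactate_peak", 2), la_base + 0.5)
  peak_minute <- sample(c(3, 5), 1)

  structure(
    list(
      subject_id = sprintf("S%02d", index),
      mass = mass,
      true_kinetics_on = on,
      true_kinetics_off = off,
      baseline_vo2_rate = a0_rate,
      durations = c(baseline_s = spec$baseline_s, exercise_s = dur_ex,
                    recovery_s = spec$recovery_s),
      lactate = list(baseline = la_base, peak = la_peak,
                     peak_minute = peak_minute),
      glucose = c(baseline = draw("glucose_baseline", 40),
                  post = draw("glucose_post", 40)),
      rpe = c(baseline = min(max(round(draw("rpe_baseline", -Inf)), 6), 20),
              post = min(max(round(draw("rpe_post", -Inf)), 6), 20)),
      noise = list(
        vo2_sd = max(p$vo2_sd[1] + if (p$vo2_sd[2] > 0) stats::rnorm(1, 0, p$vo2_sd[2]) else 0, 0),
        breath_interval_shape = 8,
        breath_interval_mean_s = c(baseline = 2.4, exercise = 1.2, recovery = 1.5),
        artifact_rate = spec$artifact_rate
      ),
      seed = seed
    ),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile %s> mass %.1f kg, exercise %.0f s\n",
              x$subject_id, x$mass, x$durations[["exercise_s"]]))
  print(x$true_kinetics_on)
  invisible(x)
}

# smooth invented ancillary-channel profiles (saturating exponentials per
# phase); values chosen to sit in plausible adult ranges
.ancillary <- function(phase, pt, vo2_rel) {
  rise <- function(t, lo, hi, tau) lo + (hi - lo) * (1 - exp(-t / tau))
  fall <- function(t, hi, lo, tau) lo + (hi - lo) * exp(-t / tau)
  switch(phase,
    baseline = list(hr = 72, ve = 12, fr = 16, rer = 0.85),
    exercise = list(
      hr = rise(pt, 72, 178, 30), ve = rise(pt, 12, 120, 25),
      fr = rise(pt, 16, 48, 30), rer = rise(pt, 0.9, 1.15, 40)
    ),
    recovery = list(
      hr = fall(pt, 165, 95, 90), ve = fall(pt, 110, 20, 60),
      fr = fall(pt, 45, 22, 80), rer = fall(pt, 1.3, 0.9, 250)
    )
  )
}

#' Generate a breath-by-breath series from a subject profile
#'
#' Breath times arise from gamma-distributed inter-breath intervals
#' (phase-specific mean interval, shape 8, i.e. coefficient of variation
#' about 35%). Each breath's mass-normalised VO2 is the subject's true
#' kinetics curve at phase time, plus Gaussian noise of SD
#' `noise$vo2_sd`; VO2 is stored absolute (times body mass). Artifact
#' breaths are injected with probability `artifact_rate` as upward spikes
#' of 5-10 noise SDs with the `artifact` flag set — the flag is the
#' injection log. Ancillary channels (HR, VE, fr, VT, VCO2) follow smooth
#' invented phase profiles in plausible ranges.
#'
#' @param profile A [make_subject()] profile.
#' @param seed Optional RNG seed; defaults to `profile$seed + 1`.
#' @return A `breath_series`.
#' @export
generate_breaths <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  set.seed(seed %||% (profile$seed + 1L))
  d <- profile$durations
  marks <- phase_marks(0, d[["baseline_s"]],
                       d[["baseline_s"]] + d[["exercise_s"]],
                       d[["baseline_s"]] + d[["exercise_s"]] + d[["recovery_s"]])
  shape <- profile$noise$breath_interval_shape
  mean_iv <- profile$noise$breath_interval_mean_s
  sd_rel <- profile$noise$vo2_sd
  rate <- profile$noise$artifact_rate

  rows <- list()
  for (phase in c("baseline", "exercise", "recovery")) {
    b <- phase_bounds(marks, phase)
    span <- b[2] - b[1]
    m_iv <- mean_iv[[phase]]
    n_max <- ceiling(span / m_iv * 2) + 20
    iv <- stats::rgamma(n_max, shape = shape, scale = m_iv / shape)
    pt <- cumsum(iv)
    pt <- pt[pt < span]
    if (length(pt) == 0) next

    curve <- switch(phase,
      baseline = rep(profile$true_kinetics_on$a0, length(pt)),
      exercise = model_value(pt, profile$true_kinetics_on),
      recovery = model_value(pt, profile$true_kinetics_off)
    )
    vo2_rel <- curve + stats::rnorm(length(pt), 0, sd_rel)
    artifact <- stats::runif(length(pt)) < rate
    if (any(artifact) && sd_rel > 0) {
      vo2_rel[artifact] <- curve[artifact] +
        (5 + stats::runif(sum(artifact), 0, 5)) * sd_rel
    }
    vo2_rel <- pmax(vo2_rel, 0)

    anc <- .ancillary(phase, pt, vo2_rel)
    ve <- pmax(anc$ve * (1 + stats::rnorm(length(pt), 0, 0.03)), 1)
    fr <- pmax(anc$fr * (1 + stats::rnorm(length(pt), 0, 0.03)), 5)
    rows[[phase]] <- tibble(
      time = b[1] + pt,
      vo2 = vo2_rel * profile$mass,
      vco2 = vo2_rel * profile$mass * anc$rer,
      ve = ve,
      fr = fr,
      vt = ve / fr,
      hr = pmax(anc$hr * (1 + stats::rnorm(length(pt), 0, 0.02)), 40),
      artifact = artifact
    )
  }
  breath_series(dplyr::bind_rows(rows), marks, profile$mass)
}

#' Generate a metabolic panel from a subject profile
#'
#' Builds the post-exercise lactate time course at minutes 1/3/5/7: a
#' concave rise to the profile's peak at `peak_minute`, then a decline of
#' 2% per minute (so no more than 10% below peak by minute 7). Glucose and
#' RPE are copied from the profile.
#'
#' @param profile A [make_subject()] profile.
#' @return A [metabolic_panel()].
#' @export
generate_panel <- function(profile) {
  stopifnot(inherits(profile, "subject_profile"))
  la0 <- profile$lactate$baseline
  peak <- profile$lactate$peak
  pm <- profile$lactate$peak_minute
  mins <- c(1, 3, 5, 7)
  la <- vapply(mins, function(m) {
    if (m <= pm) la0 + (peak - la0) * (m / pm)^0.7
    else peak * (1 - 0.02 * (m - pm))
  }, numeric(1))
  names(la) <- mins
  metabolic_panel(
    lactate_baseline = la0, lactate_post = la,
    glucose_baseline = profile$glucose[["baseline"]],
    glucose_post = profile$glucose[["post"]],
    rpe_baseline = profile$rpe[["baseline"]],
    rpe_post = profile$rpe[["post"]]
  )
}

#' Generate a full synthetic cohort
#'
#' Draws `spec$n` independent subjects and, for each, the breath series and
#' metabolic panel. Reproducible from `spec$master_seed`. Optionally writes
#' each subject's breath CSV + sidecar JSON (the canonical formats of
#' [read_breath_csv()]) plus a ground-truth manifest JSON to a directory.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional output directory.
#' @return A list of `spec$n` elements, each with `profile`, `series`,
#'   `panel`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- lapply(seq_len(spec$n), function(i) {
    profile <- make_subject(spec, i)
    series <- generate_breaths(profile)
    panel <- generate_panel(profile)
    attr(series, "panel") <- panel
    list(profile = profile, series = series, panel = panel)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- lapply(subjects, function(s) {
      p <- s$profile
      list(
        subject_id = p$subject_id, mass = p$mass, seed = p$seed,
        true_kinetics_on = unclass(p$true_kinetics_on),
        baseline_vo2_rate = p$baseline_vo2_rate,
        durations = as.list(p$durations),
        lactate = p$lactate
      )
    })
    for (s in subjects) {
      write_breath_csv(s$series,
                       file.path(out_dir, paste0(s$profile$subject_id, ".csv")),
                       panel = s$panel)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  subjects
}

#' Simulate a transient on a regular time grid
#'
#' Evaluates a kinetics curve at fixed sampling (default 1 Hz) with
#' optional Gaussian noise — the minimal forward model used to study
#' estimator behaviour independent of breath-timing stochasticity.
#'
#' @param params A [kinetics_params()].
#' @param duration Duration in seconds.
#' @param dt Sampling interval, s (default 1).
#' @param noise_sd Gaussian noise SD in mL·kg⁻¹·min⁻¹ (default 0).
#' @param seed Optional RNG seed.
#' @return A tibble with `t` (s) and `vo2` (mL·kg⁻¹·min⁻¹).
#' @export
simulate_transient <- function(params, duration, dt = 1, noise_sd = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = dt)
  vo2 <- model_value(t, params)
  if (noise_sd > 0) vo2 <- vo2 + stats::rnorm(length(t), 0, noise_sd)
  tibble(t = t, vo2 = vo2)
}
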