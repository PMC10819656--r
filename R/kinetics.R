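# Delayed-exponential VO2 kinetics.
#
# On-transient (exercise onset):
#   VO2(t) = A0 + H(t - TDp) * Ap  * (1 - exp(-(t - TDp)/tau_p))
#          [+ H(t - TDsc) * Asc * (1 - exp(-(t - TDsc)/tau_sc))]
# Off-transient (recovery):
#   VO2(t) = A0 - H(t - TDp) * Ap  * (1 - exp(-(t - TDp)/tau_p))
#          [- H(t - TDsc) * Asc * (1 - exp(-(t - TDsc)/tau_sc))]
# with H the Heaviside step (H(x) = 1 for x >= 0, else 0). All VO2 values
# are mass-normalised (mL·kg⁻¹·min⁻¹); t is phase time in seconds.

#' Delayed-exponential kinetics parameters
#'
#' @param a0 Baseline level, mL·kg⁻¹·min⁻¹ (for the off-transient this is
#'   the pre-recovery level the response decays from).
#' @param ap Primary-component amplitude, mL·kg⁻¹·min⁻¹ (>= 0).
#' @param tdp Primary time delay, s (>= 0).
#' @param tau_p Primary time constant, s (> 0).
#' @param asc,tdsc,tau_sc Optional slow/second-component amplitude, delay
#'   and time constant; either all present or all `NULL`. `tdsc` must be
#'   >= `tdp`.
#' @param direction `"on"` (rise) or `"off"` (decay).
#' @return An object of class `kinetics_params`.
#' @examples
#' kinetics_params(6.8, 42, 4.3, 14.2)
#' @export
kinetics_params <- function(a0, ap, tdp, tau_p,
                            asc = NULL, tdsc = NULL, tau_sc = NULL,
                            direction = c("on", "off")) {
  direction <- match.arg(direction)
  has_sc <- !is.null(asc)
  if (has_sc && (is.null(tdsc) || is.null(tau_sc))) {
    rlang::abort("slow component needs asc, tdsc and tau_sc together")
  }
  if (tau_p <= 0 || tdp < 0 || ap < 0) {
    rlang::abort("require tau_p > 0, tdp >= 0, ap >= 0")
  }
  if (has_sc && (tau_sc <= 0 || tdsc < tdp)) {
    rlang::abort("slow component requires tau_sc > 0 and tdsc >= tdp")
  }
  structure(
    list(a0 = a0, ap = ap, tdp = tdp, tau_p = tau_p,
         asc = asc, tdsc = tdsc, tau_sc = tau_sc, direction = direction),
    class = "kinetics_params"
  )
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat(sprintf(
    "<kinetics_params %s> A0 = %.2f, Ap = %.2f mL/kg/min, TDp = %.2f s, tau_p = %.2f s",
    x$direction, x$a0, x$ap, x$tdp, x$tau_p
  ))
  if (!is.null(x$asc)) {
    cat(sprintf(", Asc = %.2f, TDsc = %.2f s, tau_sc = %.2f s", x$asc, x$tdsc, x$tau_sc))
  }
  cat("\n")
  invisible(x)
}

# one delayed-exponential component; vectorised in t
.dexp_component <- function(t, amp, td, tau) {
  ifelse(t >= td, amp * (1 - exp(-(t - td) / tau)), 0)
}

#' Evaluate the delayed-exponential VO2 model
#'
#' @param t Phase time(s) in seconds (vectorised).
#' @param params A [kinetics_params()] object.
#' @return VO2 in mL·kg⁻¹·min⁻¹ at each `t`. The model is continuous at the
#'   time delays (each component's amplitude factor vanishes there).
#' @examples
#' p <- kinetics_params(6.8, 42, 4.3, 14.2)
#' model_value(c(0, 4.3, 4.3 + 14.2), p)
#' @export
model_value <- function(t, params) {
  stopifnot(inherits(params, "kinetics_params"))
  sgn <- if (params$direction == "on") 1 else -1
  y <- params$a0 + sgn * .dexp_component(t, params$ap, params$tdp, params$tau_p)
  if (!is.null(params$asc)) {
    y <- y + sgn * .dexp_component(t, params$asc, params$tdsc, params$tau_sc)
  }
  y
}

# ---- fitting engine (phase time t, mass-normalised vo2 y) -----------------

.fit_formula <- function(model, sgn) {
  if (model == "mono") {
    stats::as.formula(sprintf(
      "y ~ a0 + (%d) * (t >= tdp) * ap * (1 - exp(-(t - tdp)/tau_p))", sgn
    ))
  } else {
    stats::as.formula(sprintf(
      paste0(
        "y ~ a0 + (%d) * (t >= tdp) * ap * (1 - exp(-(t - tdp)/tau_p))",
        " + (%d) * (t >= tdsc) * asc * (1 - exp(-(t - tdsc)/tau_sc))"
      ), sgn, sgn
    ))
  }
}

.fit_bounds <- function(model, t_max) {
  lower <- c(a0 = 0, ap = 0, tdp = 0, tau_p = 0.1)
  upper <- c(a0 = Inf, ap = Inf, tdp = 30, tau_p = 120)
  if (model == "bi") {
    lower <- c(lower, asc = 0, tdsc = 0, tau_sc = 0.1)
    upper <- c(upper, asc = Inf, tdsc = max(t_max, 30), tau_sc = 600)
  }
  list(lower = lower, upper = upper)
}

# heuristic initial values from the data; direction-aware
.fit_start <- function(t, y, model, sgn) {
  n <- length(t)
  head_mu <- mean(y[seq_len(max(1, min(3, n)))])
  tail_mu <- mean(y[seq.int(max(1, n - 2), n)])
  a0 <- head_mu
  amp <- max(sgn * (tail_mu - head_mu), 1e-3)
  target10 <- a0 + sgn * 0.10 * amp
  target63 <- a0 + sgn * 0.63 * amp
  crossed <- if (sgn > 0) y >= target10 else y <= target10
  tdp <- if (any(crossed)) max(0, min(t[crossed])) else 0
  crossed63 <- if (sgn > 0) y >= target63 else y <= target63
  t63 <- if (any(crossed63)) min(t[crossed63]) else tdp + 20
  tau <- max(t63 - tdp, 1)
  st <- list(a0 = max(a0, 0), ap = amp, tdp = min(tdp, 30), tau_p = min(tau, 120))
  if (model == "bi") {
    st$asc <- 0.05 * amp
    st$tdsc <- min(st$tdp + st$tau_p * 2, max(t))
    st$tau_sc <- 60
  }
  st
}

# deterministic jitter factors for restarts (no RNG: fits must be
# reproducible from the data alone)
.restart_scales <- list(
  c(1, 1, 1, 1), c(1, 1.2, 0.5, 0.6), c(1, 0.8, 2, 1.6),
  c(0.9, 1.1, 0.2, 2.5), c(1.1, 0.9, 3, 0.4), c(1, 1, 0.05, 1)
)

.try_nls <- function(formula, data, start, lower, upper, maxiter = 200) {
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-10)
    )),
    error = function(e) NULL
  )
}

# core fit on (t, y); optional extra_start gets tried alongside the
# heuristic starts (used to seed the bi model from the mono solution)
.fit_core <- function(t, y, model = c("mono", "bi"),
                      direction = c("on", "off"),
                      extra_start = NULL, maxiter = 200) {
  model <- match.arg(model)
  direction <- match.arg(direction)
  sgn <- if (direction == "on") 1L else -1L
  npar <- if (model == "mono") 4L else 7L
  if (length(t) <= npar) {
    rlang::abort(sprintf("need more than %d points to fit the %s model", npar, model))
  }
  d <- data.frame(t = t, y = y)
  formula <- .fit_formula(model, sgn)
  bounds <- .fit_bounds(model, max(t))
  base <- .fit_start(t, y, model, sgn)

  starts <- lapply(.restart_scales, function(sc) {
    st <- base
    st$ap <- base$ap * sc[2]
    st$tdp <- min(max(base$tdp * sc[3], 0), 30)
    st$tau_p <- min(max(base$tau_p * sc[4], 0.1), 120)
    st
  })
  if (!is.null(extra_start)) starts <- c(list(extra_start), starts)

  best <- NULL
  for (st in starts) {
    st <- as.list(pmin(pmax(unlist(st), bounds$lower), bounds$upper))
    fit <- .try_nls(formula, d, st, bounds$lower, bounds$upper, maxiter)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(list(coef = NULL, rss = NA_real_, fitted = NULL,
                residuals = NULL, converged = FALSE))
  }
  list(
    coef = stats::coef(best$fit),
    rss = best$rss,
    fitted = as.numeric(stats::fitted(best$fit)),
    residuals = as.numeric(stats::resid(best$fit)),
    converged = TRUE
  )
}

.coef_to_params <- function(coef, model, direction) {
  if (model == "mono") {
    kinetics_params(coef[["a0"]], coef[["ap"]], coef[["tdp"]], coef[["tau_p"]],
                    direction = direction)
  } else {
    # a converged bi fit may place tdsc slightly before tdp; order the
    # components so the params object stays valid
    if (coef[["tdsc"]] < coef[["tdp"]]) {
      coef[c("ap", "tdp", "tau_p", "asc", "tdsc", "tau_sc")] <-
        coef[c("asc", "tdsc", "tau_sc", "ap", "tdp", "tau_p")]
    }
    kinetics_params(coef[["a0"]], coef[["ap"]], coef[["tdp"]], coef[["tau_p"]],
                    asc = coef[["asc"]], tdsc = coef[["tdsc"]],
                    tau_sc = coef[["tau_sc"]], direction = direction)
  }
}

#' Fit delayed-exponential kinetics to a sampled VO2 time course
#'
#' The fitting engine behind [fit_transient()], exposed for data that is
#' already expressed as phase time versus mass-normalised VO2 (e.g. a
#' simulated transient from [simulate_transient()]). Points with
#' `t < exclude` are omitted before fitting.
#'
#' @param t Phase time, seconds (re-zeroed at phase onset).
#' @param vo2 Mass-normalised VO2, mL·kg⁻¹·min⁻¹.
#' @param model `"mono"` or `"bi"`.
#' @param direction `"on"` (rising transient) or `"off"` (decay).
#' @param exclude Seconds of phase time to omit from the start (default 0).
#' @return A `kinetics_fit` (see [fit_transient()]).
#' @export
fit_vo2_kinetics <- function(t, vo2, model = c("mono", "bi"),
                             direction = c("on", "off"), exclude = 0) {
  model <- match.arg(model)
  direction <- match.arg(direction)
  keep <- t >= exclude
  t <- t[keep]; y <- vo2[keep]
  if (length(t) < 5) {
    rlang::abort("fewer than 5 usable points after exclusion")
  }
  extra <- NULL
  if (model == "bi") {
    mono <- .fit_core(t, y, "mono", direction)
    if (mono$converged) {
      cf <- mono$coef
      extra <- list(a0 = cf[["a0"]], ap = cf[["ap"]], tdp = cf[["tdp"]],
                    tau_p = cf[["tau_p"]], asc = 0,
                    tdsc = min(cf[["tdp"]] + 2 * cf[["tau_p"]], max(t)),
                    tau_sc = 60)
    }
  }
  res <- .fit_core(t, y, model, direction, extra_start = extra)
  .as_kinetics_fit(res, t, y, model, direction, phase = NA_character_,
                   exclude = exclude)
}

.as_kinetics_fit <- function(res, t, y, model, direction, phase, exclude) {
  if (!res$converged) {
    rlang::warn("kinetics fit did not converge; returning diagnostics only")
    return(structure(
      list(params = NULL, coef = NULL, rss = NA_real_, n_points = length(t),
           residuals = NULL, fitted = NULL, data = tibble(t = t, y = y),
           model = model, direction = direction, phase = phase,
           exclude = exclude, converged = FALSE,
           bootstrap = NULL, ci95 = NULL),
      class = "kinetics_fit"
    ))
  }
  structure(
    list(
      params = .coef_to_params(res$coef, model, direction),
      coef = res$coef,
      rss = res$rss,
      n_points = length(t),
      residuals = res$residuals,
      fitted = res$fitted,
      data = tibble(t = t, y = y),
      model = model,
      direction = direction,
      phase = phase,
      exclude = exclude,
      converged = TRUE,
      bootstrap = NULL,
      ci95 = NULL
    ),
    class = "kinetics_fit"
  )
}

#' Fit delayed-exponential kinetics to an exercise or recovery transient
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints) of
#' the mono- or bi-exponential delayed model to mass-normalised VO2 versus
#' phase time. Exercise fits the on-transient (rise), recovery the
#' off-transient (decay). The first `exclude` seconds of phase time are
#' omitted to discard the cardiodynamic phase, whose VO2 rise reflects
#' increased pulmonary blood flow rather than muscle O2 extraction; note
#' that a non-zero exclusion interacts with the estimability of short time
#' delays. Several deterministic heuristic starts are tried and the best
#' (lowest-RSS) converged solution is kept, so the fit is reproducible from
#' the data alone. The bi model is additionally seeded from the mono
#' solution, which guarantees its RSS is no worse.
#'
#' @param series A `breath_series` (raw, cleaned or binned).
#' @param phase `"exercise"` or `"recovery"`.
#' @param model `"mono"` or `"bi"`.
#' @param exclude Cardiodynamic exclusion window in seconds of phase time
#'   (default 20; use 0 to fit from phase onset).
#' @return An object of class `kinetics_fit`: parameters, RSS, residuals,
#'   fitted values, the (t, y) data fitted, and a `converged` flag.
#' @seealso [bootstrap_fit()] for confidence intervals.
#' @export
fit_transient <- function(series, phase = c("exercise", "recovery"),
                          model = c("mono", "bi"), exclude = 20) {
  stopifnot(inherits(series, "breath_series"))
  phase <- match.arg(phase)
  model <- match.arg(model)
  direction <- if (phase == "exercise") "on" else "off"
  sl <- slice_phase(series, phase, rezero = TRUE)
  fit <- fit_vo2_kinetics(sl$records$time, sl$records$vo2 / series$body_mass,
                          model = model, direction = direction,
                          exclude = exclude)
  fit$phase <- phase
  fit
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> %s %s-transient, %d points, exclude %g s\n",
              x$model, x$direction, x$n_points, x$exclude))
  if (!x$converged) {
    cat("  (not converged)\n")
    return(invisible(x))
  }
  print(x$params)
  cat(sprintf("  RSS = %.4g", x$rss))
  if (!is.null(x$ci95)) {
    cat(sprintf("; 95%% CI (B = %d), e.g. tau_p [%.2f, %.2f] s",
                nrow(x$bootstrap), x$ci95["tau_p", 1], x$ci95["tau_p", 2]))
  }
  cat("\n")
  invisible(x)
}

#' Residual-resampling bootstrap for a kinetics fit
#'
#' Builds `b` synthetic datasets as fitted curve + residuals resampled with
#' replacement, refits each from the point estimate, and stores the
#' empirical parameter distribution with percentile 95% confidence
#' intervals. Residual (rather than case) resampling preserves the time
#' grid of a single subject's transient. Reproducible for a fixed seed.
#'
#' @param fit A converged `kinetics_fit`.
#' @param b Number of bootstrap samples (default 1000).
#' @param seed Integer seed for the resampling RNG.
#' @return The fit with `bootstrap` (b x npar matrix) and `ci95` (npar x 2
#'   matrix of 2.5th/97.5th percentiles) filled in; a warning is recorded in
#'   `boot_diagnostics` if more than 20% of refits fail to converge.
#' @export
bootstrap_fit <- function(fit, b = 1000, seed = NULL) {
  stopifnot(inherits(fit, "kinetics_fit"))
  if (!fit$converged) rlang::abort("cannot bootstrap a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  n <- length(fit$residuals)
  sgn <- if (fit$direction == "on") 1L else -1L
  formula <- .fit_formula(fit$model, sgn)
  bounds <- .fit_bounds(fit$model, max(fit$data$t))
  start <- as.list(fit$coef)
  est <- matrix(NA_real_, nrow = b, ncol = length(fit$coef),
                dimnames = list(NULL, names(fit$coef)))
  n_fail <- 0L
  for (i in seq_len(b)) {
    yb <- fit$fitted + sample(fit$residuals, n, replace = TRUE)
    fb <- .try_nls(formula, data.frame(t = fit$data$t, y = yb),
                   start, bounds$lower, bounds$upper, maxiter = 60)
    if (is.null(fb)) {
      n_fail <- n_fail + 1L
      next
    }
    est[i, ] <- stats::coef(fb)
  }
  ok <- stats::complete.cases(est)
  if (n_fail > 0.2 * b) {
    rlang::warn(sprintf("%d of %d bootstrap refits failed to converge", n_fail, b))
  }
  ci <- t(apply(est[ok, , drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  fit$bootstrap <- est
  fit$ci95 <- ci
  fit$boot_diagnostics <- list(b = b, n_failed = n_fail, seed = seed)
  fit
}

# trapezoidal integral of net (above-baseline, clipped at 0) VO2 in litres.
# times in s, vo2 absolute mL/min, baseline_rate L/min.
.net_o2_integral <- function(time_s, vo2_ml_min, baseline_rate) {
  if (baseline_rate <= 0) {
    rlang::abort("baseline_rate must be positive (L/min)")
  }
  net <- pmax(vo2_ml_min / 1000 - baseline_rate, 0) # L/min
  if (length(time_s) < 2) return(0)
  pracma::trapz(time_s, net) / 60 # (L/min)*s -> L
}

#' Accumulated VO2 over the exercise phase
#'
#' Integrates net VO2 — instantaneous VO2 minus the baseline rate, clipped
#' at zero so breath noise below baseline cannot contribute negative volume
#' — over the exercise phase by the trapezoid rule, and divides by the
#' exercise duration to express the accumulation per unit time.
#'
#' @param series A `breath_series`.
#' @param baseline_rate Baseline VO2 rate in L·min⁻¹ (typically the
#'   baseline-phase mean, see [phase_mean_rate()]).
#' @param phase Phase to integrate over (default `"exercise"`).
#' @return A list with `net_volume_l` (L) and `mean_net_rate_l_min`
#'   (L·min⁻¹ = net volume over phase duration).
#' @export
accumulated_vo2 <- function(series, baseline_rate, phase = "exercise") {
  stopifnot(inherits(series, "breath_series"))
  sl <- slice_phase(series, phase, rezero = TRUE)
  if (nrow(sl$records) == 0) rlang::abort(sprintf("phase '%s' is empty", phase))
  b <- phase_bounds(series$marks, phase)
  vol <- .net_o2_integral(sl$records$time, sl$records$vo2, baseline_rate)
  dur_min <- (b[2] - b[1]) / 60
  list(net_volume_l = vol, mean_net_rate_l_min = vol / dur_min)
}

#' Excess post-exercise oxygen consumption (EPOC)
#'
#' Trapezoidal integral of VO2 above the baseline rate (clipped at zero)
#' over the first `window_s` seconds of recovery.
#'
#' @param series A `breath_series`.
#' @param baseline_rate Baseline VO2 rate, L·min⁻¹ (> 0).
#' @param window_s Recovery window in seconds (default 300 = 5 min).
#' @return EPOC volume in litres. Monotone non-decreasing in `window_s`.
#' @export
epoc <- function(series, baseline_rate, window_s = 300) {
  stopifnot(inherits(series, "breath_series"), window_s > 0)
  sl <- slice_phase(series, "recovery", rezero = TRUE)
  rec <- sl$records[sl$records$time <= window_s, , drop = FALSE]
  if (nrow(rec) == 0) rlang::abort("recovery phase is empty")
  .net_o2_integral(rec$time, rec$vo2, baseline_rate)
}

#' Mean absolute VO2 rate over a phase
#'
#' Convenience accessor used to obtain the baseline rate for the net-VO2
#' integrals.
#'
#' @param series A `breath_series`.
#' @param phase Phase name (default `"baseline"`).
#' @return Mean VO2 over the phase's breaths, in L·min⁻¹.
#' @export
phase_mean_rate <- function(series, phase = "baseline") {
  sl <- slice_phase(series, phase)
  if (nrow(sl$records) == 0) rlang::abort(sprintf("phase '%s' is empty", phase))
  mean(sl$records$vo2) / 1000
}
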