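# Energy-system partitioning: oxidative (net VO2 integral), glycolytic
# (net blood-lactate O2 equivalent), phosphagen (phosphocreatine
# splitting), totals, fractions, metabolic power and caloric expenditure.

#' Physiological conversion constants for the energy partition
#'
#' All constants are overridable so sensitivity to the assumed physiology
#' can be explored; every [total_breakdown()] result echoes the constants
#' that produced it.
#'
#' @param beta O2 equivalent of blood lactate accumulation,
#'   mL·kg⁻¹·mM⁻¹ (default 3).
#' @param e_o2 Energy equivalent of oxygen, kJ·L⁻¹ (default 20.9).
#' @param pcr_rest Resting muscle phosphocreatine store, mmol·kg⁻¹
#'   (default 18.5).
#' @param tau_pcr Time constant of phosphocreatine splitting at exercise
#'   onset, s (default 23.4).
#' @param k_pcr Energy equivalent of phosphocreatine, kJ·mmol⁻¹
#'   (default 0.468).
#' @param po_ratio Phosphate/oxygen ratio: mmol high-energy phosphate
#'   resynthesised per mmol O2 (default 6.25).
#' @param kcal_per_l Caloric equivalent of oxygen, kcal·L⁻¹ (default 5.05).
#' @param kj_per_kcal kJ per kcal (default 4.184).
#' @param molar_vol_o2 Molar volume of O2, mL·mmol⁻¹ (default 22.4).
#' @return An object of class `energy_constants`.
#' @export
energy_constants <- function(beta = 3, e_o2 = 20.9, pcr_rest = 18.5,
                             tau_pcr = 23.4, k_pcr = 0.468, po_ratio = 6.25,
                             kcal_per_l = 5.05, kj_per_kcal = 4.184,
                             molar_vol_o2 = 22.4) {
  x <- list(
    beta = beta, e_o2 = e_o2, pcr_rest = pcr_rest, tau_pcr = tau_pcr,
    k_pcr = k_pcr, po_ratio = po_ratio, kcal_per_l = kcal_per_l,
    kj_per_kcal = kj_per_kcal, molar_vol_o2 = molar_vol_o2
  )
  v <- unlist(x)
  if (any(!is.finite(v)) || any(v <= 0)) {
    rlang::abort("all energy constants must be strictly positive")
  }
  structure(x, class = "energy_constants")
}

#' @export
print.energy_constants <- function(x, ...) {
  cat("<energy_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Oxidative-pathway energy from a net O2 volume
#'
#' @param net_o2_l Net (above-baseline) O2 volume consumed during the
#'   effort, litres (>= 0); typically `accumulated_vo2()$net_volume_l`.
#' @param constants An [energy_constants()] object.
#' @return Energy in kJ (`net_o2_l * e_o2`).
#' @export
oxidative_energy <- function(net_o2_l, constants = energy_constants()) {
  if (!is.finite(net_o2_l) || net_o2_l < 0) {
    rlang::abort("net_o2_l must be non-negative")
  }
  net_o2_l * constants$e_o2
}

#' Glycolytic-pathway energy from net blood-lactate accumulation
#'
#' Net lactate is the peak of the post-exercise samples minus baseline,
#' floored at zero. Its O2 equivalent is `la_net * beta * mass` (mL,
#' reported in litres) and the energy is that volume times the O2 energy
#' equivalent.
#'
#' @param la_baseline Baseline blood lactate, mM.
#' @param la_post Post-exercise lactate samples, mM (vector or the
#'   `lactate_post` field of a [metabolic_panel()]).
#' @param mass Body mass, kg (> 0).
#' @param constants An [energy_constants()] object.
#' @param muscle_fraction Optional active-muscle-mass multiplier applied to
#'   `mass` (default 1, i.e. whole-body mass as the reference basis).
#' @return A list with `la_net_mm`, `o2_equiv_l` and `energy_kj`.
#' @export
glycolytic_energy <- function(la_baseline, la_post, mass,
                              constants = energy_constants(),
                              muscle_fraction = 1) {
  if (length(la_post) < 1) rlang::abort("need at least one post-exercise lactate sample")
  if (mass <= 0) rlang::abort("mass must be positive")
  la_net <- max(max(la_post) - la_baseline, 0)
  o2_ml <- la_net * constants$beta * mass * muscle_fraction
  list(
    la_net_mm = la_net,
    o2_equiv_l = o2_ml / 1000,
    energy_kj = o2_ml / 1000 * constants$e_o2
  )
}

#' Phosphagen-pathway energy from phosphocreatine splitting
#'
#' Models whole-body phosphocreatine splitting as a single exponential with
#' time constant `tau_pcr` from a resting store of `pcr_rest`:
#' `split = pcr_rest * (1 - exp(-duration/tau_pcr)) * mass` (mmol). Two
#' energy conventions are available, because the underlying constants
#' (an energy equivalent per mmol PCr and a phosphate/oxygen ratio) imply
#' very different scalings and field usage varies:
#' \describe{
#'   \item{`"o2_equivalent"` (default)}{converts the split to an O2 volume
#'     via the P/O ratio and molar volume, then to kJ at the O2 energy
#'     equivalent: `(split / po_ratio) * molar_vol_o2 / 1000 * e_o2`.}
#'   \item{`"direct_kj"`}{multiplies the split by the PCr energy
#'     equivalent: `k_pcr * split`.}
#' }
#' Results always carry the convention used; see the package vignette for
#' why neither convention should be compared across studies without
#' checking the mass basis.
#'
#' @param duration_s Effort duration, s (>= 0).
#' @param mass Body mass, kg (> 0).
#' @param convention `"o2_equivalent"` or `"direct_kj"`.
#' @param constants An [energy_constants()] object.
#' @param muscle_fraction Optional active-muscle-mass multiplier (default 1).
#' @return Energy in kJ, with attribute `convention`.
#' @export
phosphagen_energy <- function(duration_s, mass,
                              convention = c("o2_equivalent", "direct_kj"),
                              constants = energy_constants(),
                              muscle_fraction = 1) {
  convention <- match.arg(convention)
  if (duration_s < 0) rlang::abort("duration_s must be non-negative")
  if (mass <= 0) rlang::abort("mass must be positive")
  split_mmol <- constants$pcr_rest * (1 - exp(-duration_s / constants$tau_pcr)) *
    mass * muscle_fraction
  e <- switch(convention,
    direct_kj = constants$k_pcr * split_mmol,
    o2_equivalent = split_mmol / constants$po_ratio * constants$molar_vol_o2 / 1000 *
      constants$e_o2
  )
  structure(e, convention = convention)
}

#' Caloric expenditure from an O2 volume
#'
#' @param o2_l O2 volume in litres (>= 0).
#' @param constants An [energy_constants()] object.
#' @return Energy in kJ: `o2_l * kcal_per_l * kj_per_kcal`.
#' @export
caloric_expenditure <- function(o2_l, constants = energy_constants()) {
  if (!is.finite(o2_l) || o2_l < 0) rlang::abort("o2_l must be non-negative")
  o2_l * constants$kcal_per_l * constants$kj_per_kcal
}

#' Assemble an energy breakdown from the three pathway energies
#'
#' @param oxidative_kj,glycolytic_kj,phosphagen_kj Pathway energies, kJ
#'   (>= 0, not all zero).
#' @param duration_s Effort duration, s (> 0); metabolic power is
#'   `total_kj / duration_s` (kJ/s = kW).
#' @param convention_tag Label recording which phosphagen convention
#'   produced `phosphagen_kj`.
#' @param caloric_workout_kj,caloric_recovery_kj Optional caloric
#'   expenditure figures to carry along.
#' @return An object of class `energy_breakdown` with the three energies,
#'   `total_kj`, `fractions` (summing to 1), and `metabolic_power_kw`.
#' @export
energy_breakdown <- function(oxidative_kj, glycolytic_kj, phosphagen_kj,
                             duration_s, convention_tag = "explicit",
                             caloric_workout_kj = NA_real_,
                             caloric_recovery_kj = NA_real_) {
  e <- c(oxidative = oxidative_kj, glycolytic = glycolytic_kj,
         phosphagen = phosphagen_kj)
  if (any(!is.finite(e)) || any(e < 0)) {
    rlang::abort("pathway energies must be non-negative")
  }
  total <- sum(e)
  if (total <= 0) rlang::abort("total energy is zero; fractions undefined")
  if (duration_s <= 0) rlang::abort("duration_s must be positive")
  structure(
    list(
      oxidative_kj = oxidative_kj,
      glycolytic_kj = glycolytic_kj,
      phosphagen_kj = phosphagen_kj,
      total_kj = total,
      fractions = e / total,
      duration_s = duration_s,
      metabolic_power_kw = total / duration_s,
      caloric_workout_kj = caloric_workout_kj,
      caloric_recovery_kj = caloric_recovery_kj,
      convention_tag = convention_tag
    ),
    class = "energy_breakdown"
  )
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown>\n")
  cat(sprintf("  oxidative   %7.1f kJ (%4.1f%%)\n", x$oxidative_kj, 100 * x$fractions[["oxidative"]]))
  cat(sprintf("  glycolytic  %7.1f kJ (%4.1f%%)\n", x$glycolytic_kj, 100 * x$fractions[["glycolytic"]]))
  cat(sprintf("  phosphagen  %7.1f kJ (%4.1f%%)  [%s]\n", x$phosphagen_kj,
              100 * x$fractions[["phosphagen"]], x$convention_tag))
  cat(sprintf("  total       %7.1f kJ over %.0f s -> %.2f kW\n",
              x$total_kj, x$duration_s, x$metabolic_power_kw))
  if (is.finite(x$caloric_workout_kj)) {
    cat(sprintf("  caloric: workout %.1f kJ", x$caloric_workout_kj))
    if (is.finite(x$caloric_recovery_kj)) {
      cat(sprintf(", recovery %.1f kJ", x$caloric_recovery_kj))
    }
    cat("\n")
  }
  invisible(x)
}

#' Full energy-system partition for one effort
#'
#' Composes the three pathway estimates: oxidative from the net exercise
#' O2 volume, glycolytic from the metabolic panel's net lactate, and
#' phosphagen from the effort duration. Workout caloric expenditure is
#' computed from the net exercise O2 volume and, if `epoc_l` is supplied,
#' recovery caloric expenditure from the EPOC volume. EPOC is reported
#' separately and not added to the workout total.
#'
#' @param net_o2_exercise_l Net exercise O2 volume, litres.
#' @param panel A [metabolic_panel()] (or a list with `lactate_baseline`
#'   and `lactate_post`).
#' @param duration_s Exercise duration, s.
#' @param mass Body mass, kg.
#' @param convention Phosphagen convention, see [phosphagen_energy()].
#' @param constants An [energy_constants()] object; echoed in the result.
#' @param epoc_l Optional recovery EPOC volume, litres.
#' @param muscle_fraction Optional active-muscle-mass multiplier (default 1).
#' @return An `energy_breakdown` with the constants attached as attribute
#'   `"constants"`.
#' @export
total_breakdown <- function(net_o2_exercise_l, panel, duration_s, mass,
                            convention = c("o2_equivalent", "direct_kj"),
                            constants = energy_constants(),
                            epoc_l = NULL, muscle_fraction = 1) {
  convention <- match.arg(convention)
  ox <- oxidative_energy(net_o2_exercise_l, constants)
  gl <- glycolytic_energy(panel$lactate_baseline, panel$lactate_post, mass,
                          constants, muscle_fraction)
  ph <- phosphagen_energy(duration_s, mass, convention, constants,
                          muscle_fraction)
  out <- energy_breakdown(
    ox, gl$energy_kj, as.numeric(ph), duration_s,
    convention_tag = convention,
    caloric_workout_kj = caloric_expenditure(net_o2_exercise_l, constants),
    caloric_recovery_kj = if (is.null(epoc_l)) NA_real_ else
      caloric_expenditure(epoc_l, constants)
  )
  attr(out, "constants") <- constants
  out
}

#' Repetition frequency of a scored workout
#'
#' @param reps Number of repetitions completed.
#' @param duration_s Time taken, seconds (> 0).
#' @return Repetitions per second.
#' @examples
#' rep_frequency(30, 117)
#' @export
rep_frequency <- function(reps, duration_s) {
  if (duration_s <= 0) rlang::abort("duration_s must be positive")
  reps / duration_s
}
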