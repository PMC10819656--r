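#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble is_tibble
NULL

# Canonical cardiorespiratory channels carried on every breath record.
.breath_channels <- c("vo2", "vco2", "ve", "fr", "vt", "hr")

# Canonical CSV column names (see read_breath_csv).
.canonical_cols <- c(
  time = "time_s", vo2 = "vo2_ml_min", vco2 = "vco2_ml_min",
  ve = "ve_l_min", fr = "fr_bpm", vt = "vt_l", hr = "hr_bpm",
  artifact = "artifact"
)

#' Phase marks for a gas-exchange session
#'
#' A session is segmented into three contiguous phases — resting baseline,
#' exercise, and recovery — by four time marks (seconds from session start).
#' Phases are half-open intervals `[start, end)` so that a breath falling
#' exactly on a boundary belongs to the later phase and is never counted
#' twice.
#'
#' @param baseline_start,exercise_start,exercise_end,recovery_end Strictly
#'   increasing times in seconds.
#' @return An object of class `phase_marks`.
#' @examples
#' phase_marks(0, 120, 237, 657)
#' @export
phase_marks <- function(baseline_start, exercise_start, exercise_end,
                        recovery_end) {
  m <- list(
    baseline_start = as.numeric(baseline_start),
    exercise_start = as.numeric(exercise_start),
    exercise_end = as.numeric(exercise_end),
    recovery_end = as.numeric(recovery_end)
  )
  v <- unlist(m)
  if (any(!is.finite(v))) {
    abort("phase marks must be finite numbers")
  }
  if (!all(diff(v) > 0)) {
    abort("phase marks must be strictly increasing: baseline_start < exercise_start < exercise_end < recovery_end")
  }
  structure(m, class = "phase_marks")
}

#' @export
print.phase_marks <- function(x, ...) {
  cat(sprintf(
    "<phase_marks> baseline [%g, %g) | exercise [%g, %g) | recovery [%g, %g)\n",
    x$baseline_start, x$exercise_start, x$exercise_start, x$exercise_end,
    x$exercise_end, x$recovery_end
  ))
  invisible(x)
}

# start/end of one phase as c(start, end)
phase_bounds <- function(marks, phase) {
  switch(phase,
    baseline = c(marks$baseline_start, marks$exercise_start),
    exercise = c(marks$exercise_start, marks$exercise_end),
    recovery = c(marks$exercise_end, marks$recovery_end),
    abort(sprintf("unknown phase '%s'", phase))
  )
}

#' Breath-by-breath gas-exchange series
#'
#' The pipeline's main carrier: an ordered collection of breath records with
#' the session's phase marks and the subject's body mass. VO2 and VCO2 are
#' stored in absolute mL·min⁻¹; mass-normalisation (mL·kg⁻¹·min⁻¹) is
#' applied at presentation and fitting time because the energy integrals
#' need absolute volumes.
#'
#' @param records A data frame with columns `time` (s from session start)
#'   and `vo2` (mL·min⁻¹); optionally `vco2` (mL·min⁻¹), `ve` (L·min⁻¹),
#'   `fr` (breaths·min⁻¹), `vt` (L), `hr` (beats·min⁻¹) and `artifact`
#'   (logical flag for breaths to exclude, e.g. coughs or signal dropouts;
#'   defaults to `FALSE`). Times must be strictly increasing and lie within
#'   `[baseline_start, recovery_end]`.
#' @param marks A [phase_marks()] object.
#' @param body_mass Subject body mass in kg (> 0).
#' @return An object of class `breath_series`: a list with elements
#'   `records` (tibble), `marks` and `body_mass`.
#' @examples
#' breath_series(
#'   tibble::tibble(time = c(1, 3, 5), vo2 = c(400, 420, 410)),
#'   phase_marks(0, 2, 4, 6), body_mass = 80
#' )
#' @export
breath_series <- function(records, marks, body_mass) {
  stopifnot(inherits(marks, "phase_marks"))
  records <- as_tibble(records)
  if (!all(c("time", "vo2") %in% names(records))) {
    abort("records must contain at least 'time' and 'vo2' columns")
  }
  for (ch in .breath_channels) {
    if (!ch %in% names(records)) records[[ch]] <- NA_real_
    records[[ch]] <- as.numeric(records[[ch]])
  }
  if (!"artifact" %in% names(records)) records$artifact <- FALSE
  records$artifact <- as.logical(records$artifact)
  records$artifact[is.na(records$artifact)] <- FALSE
  records$time <- as.numeric(records$time)
  records <- records[, c("time", .breath_channels, "artifact")]

  x <- structure(
    list(records = records, marks = marks, body_mass = as.numeric(body_mass)),
    class = "breath_series"
  )
  validate_breath_series(x)
}

#' Validate a breath series
#'
#' Checks the structural invariants: strictly increasing times, all times
#' within the session window, non-negative channel values and positive body
#' mass.
#'
#' @param x A `breath_series`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_breath_series <- function(x) {
  stopifnot(inherits(x, "breath_series"))
  r <- x$records
  if (!is.finite(x$body_mass) || x$body_mass <= 0) {
    abort("body_mass must be a positive number (kg)")
  }
  if (nrow(r) > 0) {
    if (any(!is.finite(r$time))) abort("breath times must be finite")
    bad <- which(diff(r$time) <= 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "breath times must be strictly increasing; first violation at row %d (time %g after %g)",
        bad[1] + 1, r$time[bad[1] + 1], r$time[bad[1]]
      ))
    }
    if (any(r$time < x$marks$baseline_start | r$time > x$marks$recovery_end)) {
      abort("all breath times must lie within [baseline_start, recovery_end]")
    }
    for (ch in .breath_channels) {
      v <- r[[ch]]
      if (any(v[!is.na(v)] < 0)) {
        abort(sprintf("channel '%s' must be non-negative", ch))
      }
    }
  }
  x
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf(
    "<breath_series> %d breaths over [%g, %g] s, body mass %.1f kg\n",
    nrow(x$records), x$marks$baseline_start, x$marks$recovery_end, x$body_mass
  ))
  print(x$marks)
  print(utils::head(x$records, 5))
  if (nrow(x$records) > 5) cat(sprintf("# ... with %d more breaths\n", nrow(x$records) - 5))
  invisible(x)
}

#' Number of breaths in a series
#' @param x A `breath_series`.
#' @return Integer count of breath records.
#' @export
n_breaths <- function(x) {
  stopifnot(inherits(x, "breath_series"))
  nrow(x$records)
}

#' Metabolic panel: blood lactate, glucose and perceived exertion
#'
#' Holds the pre/post blood measures sampled around a workout: baseline
#' lactate, post-exercise lactate at the 1st/3rd/5th/7th minute of recovery,
#' baseline and post glucose, and Borg 6-20 ratings of perceived exertion.
#'
#' @param lactate_baseline Baseline blood lactate, mM (> 0).
#' @param lactate_post Named numeric vector of post-exercise lactate (mM),
#'   names being recovery minutes from `{1, 3, 5, 7}`.
#' @param glucose_baseline,glucose_post Blood glucose, mg·dL⁻¹ (> 0).
#' @param rpe_baseline,rpe_post Borg-scale ratings of perceived exertion,
#'   integers in 6-20.
#' @return An object of class `metabolic_panel`.
#' @examples
#' metabolic_panel(1.5, c(`1` = 15, `3` = 19, `5` = 20.7, `7` = 19.8),
#'                 97.1, 141.8, 6, 18)
#' @export
metabolic_panel <- function(lactate_baseline, lactate_post,
                            glucose_baseline, glucose_post,
                            rpe_baseline, rpe_post) {
  lactate_post <- unlist(lactate_post)
  if (is.null(names(lactate_post)) || any(!names(lactate_post) %in% c("1", "3", "5", "7"))) {
    abort("lactate_post must be named by recovery minute, from {1, 3, 5, 7}")
  }
  conc <- c(lactate_baseline, lactate_post, glucose_baseline, glucose_post)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("all lactate and glucose concentrations must be positive")
  }
  rpe <- c(rpe_baseline, rpe_post)
  if (any(rpe < 6 | rpe > 20)) {
    abort("RPE must lie on the Borg 6-20 scale")
  }
  structure(
    list(
      lactate_baseline = as.numeric(lactate_baseline),
      lactate_post = lactate_post,
      glucose_baseline = as.numeric(glucose_baseline),
      glucose_post = as.numeric(glucose_post),
      rpe_baseline = as.integer(rpe_baseline),
      rpe_post = as.integer(rpe_post)
    ),
    class = "metabolic_panel"
  )
}

#' @export
print.metabolic_panel <- function(x, ...) {
  cat(sprintf(
    "<metabolic_panel> lactate %.1f -> peak %.1f mM | glucose %.1f -> %.1f mg/dL | RPE %d -> %d\n",
    x$lactate_baseline, max(x$lactate_post), x$glucose_baseline,
    x$glucose_post, x$rpe_baseline, x$rpe_post
  ))
  invisible(x)
}

#' Read a breath-by-breath CSV with its sidecar session file
#'
#' Reads a comma-separated breath file (UTF-8, header row, '.' decimal)
#' whose canonical columns are `time_s`, `vo2_ml_min`, `vco2_ml_min`,
#' `ve_l_min`, `fr_bpm`, `vt_l`, `hr_bpm` and optionally `artifact`.
#' Vendor exports with other headers are handled through `dialect`, a named
#' character vector mapping canonical names to the file's column names.
#' Phase marks and body mass come from a sidecar JSON file (by default the
#' CSV path with extension `.json`) with fields `marks` (the four phase
#' times) and `body_mass`; an optional `panel` field is read into a
#' [metabolic_panel()].
#'
#' Rows whose `time` or `vo2` entries are not numeric are dropped with a
#' warning reporting their row numbers; non-monotone times are an error
#' naming the first offending row.
#'
#' @param path Path to the breath CSV.
#' @param dialect Optional named character vector, e.g.
#'   `c(time_s = "t(sec)", vo2_ml_min = "VO2")`.
#' @param sidecar Path to the sidecar JSON; default swaps the CSV extension
#'   for `.json`.
#' @return A [breath_series()]; if the sidecar carried a metabolic panel it
#'   is attached as attribute `"panel"`.
#' @seealso [write_breath_csv()]
#' @export
read_breath_csv <- function(path, dialect = NULL, sidecar = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  sidecar <- sidecar %||% paste0(sub("\\.[Cc][Ss][Vv]$", "", path), ".json")
  if (!file.exists(sidecar)) {
    abort(sprintf("sidecar session file not found: %s", sidecar))
  }
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$marks) || is.null(side$body_mass)) {
    abort("sidecar must provide 'marks' and 'body_mass'")
  }
  marks <- phase_marks(
    side$marks$baseline_start, side$marks$exercise_start,
    side$marks$exercise_end, side$marks$recovery_end
  )

  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  cols <- .canonical_cols
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      key <- names(.canonical_cols)[.canonical_cols == canon]
      if (length(key) == 0) abort(sprintf("unknown canonical column in dialect: '%s'", canon))
      cols[key] <- dialect[[canon]]
    }
  }
  for (req in c("time", "vo2")) {
    if (!cols[[req]] %in% names(raw)) {
      abort(sprintf("required column '%s' missing from %s", cols[[req]], path))
    }
  }

  n <- nrow(raw)
  get_num <- function(key) {
    if (!cols[[key]] %in% names(raw)) return(rep(NA_real_, n))
    suppressWarnings(as.numeric(raw[[cols[[key]]]]))
  }
  time <- get_num("time")
  vo2 <- get_num("vo2")
  bad_rows <- which(is.na(time) | is.na(vo2))
  if (length(bad_rows) > 0) {
    warn(sprintf(
      "dropped %d row(s) with non-numeric time/vo2: rows %s",
      length(bad_rows), paste(bad_rows, collapse = ", ")
    ))
  }
  keep <- setdiff(seq_len(n), bad_rows)
  rec <- tibble(
    time = time[keep], vo2 = vo2[keep], vco2 = get_num("vco2")[keep],
    ve = get_num("ve")[keep], fr = get_num("fr")[keep],
    vt = get_num("vt")[keep], hr = get_num("hr")[keep]
  )
  if ("artifact" %in% names(cols) && cols[["artifact"]] %in% names(raw)) {
    rec$artifact <- as.logical(raw[[cols[["artifact"]]]][keep])
  }
  if (nrow(rec) > 1) {
    bad <- which(diff(rec$time) <= 0)
    if (length(bad) > 0) {
      abort(sprintf("non-monotone time in %s at row %d", path, keep[bad[1] + 1]))
    }
  }
  out <- breath_series(rec, marks, side$body_mass)
  if (!is.null(side$panel)) {
    p <- side$panel
    lp <- unlist(p$lactate_post)
    attr(out, "panel") <- metabolic_panel(
      p$lactate_baseline, lp, p$glucose_baseline, p$glucose_post,
      p$rpe_baseline, p$rpe_post
    )
  }
  out
}

#' Write a breath series to CSV plus sidecar JSON
#'
#' Inverse of [read_breath_csv()]: writes the canonical-column CSV and a
#' sidecar JSON holding phase marks, body mass and (if present) the attached
#' metabolic panel. Round-trips a valid series field-for-field.
#'
#' @param series A `breath_series`.
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param panel Optional [metabolic_panel()] to store in the sidecar;
#'   defaults to the series' `"panel"` attribute if set.
#' @return `path`, invisibly.
#' @export
write_breath_csv <- function(series, path, panel = NULL) {
  stopifnot(inherits(series, "breath_series"))
  panel <- panel %||% attr(series, "panel")
  rec <- series$records
  out <- rec
  names(out) <- c(.canonical_cols[c("time", .breath_channels)], "artifact")
  readr::write_csv(out, path, progress = FALSE)
  side <- list(
    marks = unclass(series$marks),
    body_mass = series$body_mass
  )
  if (!is.null(panel)) {
    side$panel <- list(
      lactate_baseline = panel$lactate_baseline,
      lactate_post = as.list(panel$lactate_post),
      glucose_baseline = panel$glucose_baseline,
      glucose_post = panel$glucose_post,
      rpe_baseline = panel$rpe_baseline,
      rpe_post = panel$rpe_post
    )
  }
  jsonlite::write_json(side, paste0(sub("\\.[Cc][Ss][Vv]$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract one phase of a breath series
#'
#' Returns the records whose times fall in the half-open phase interval
#' `[start, end)`. Slicing the three phases in turn therefore partitions the
#' records with no duplication. Optionally re-zeroes times to the phase
#' start (the marks are shifted consistently so the result is still a valid
#' series).
#'
#' @param series A `breath_series`.
#' @param phase One of `"baseline"`, `"exercise"`, `"recovery"`.
#' @param rezero If `TRUE`, subtract the phase start from all times and
#'   marks.
#' @return A `breath_series` containing only the phase's breaths (its marks
#'   are unchanged apart from optional re-zeroing). An empty phase yields an
#'   empty series with a warning.
#' @export
slice_phase <- function(series, phase = c("baseline", "exercise", "recovery"),
                        rezero = FALSE) {
  stopifnot(inherits(series, "breath_series"))
  phase <- match.arg(phase)
  b <- phase_bounds(series$marks, phase)
  rec <- series$records
  keep <- rec$time >= b[1] & rec$time < b[2]
  if (!any(keep)) {
    warn(sprintf("phase '%s' contains no breaths", phase))
  }
  rec <- rec[keep, , drop = FALSE]
  marks <- series$marks
  if (rezero) {
    rec$time <- rec$time - b[1]
    marks <- phase_marks(
      marks$baseline_start - b[1], marks$exercise_start - b[1],
      marks$exercise_end - b[1], marks$recovery_end - b[1]
    )
  }
  out <- series
  out$records <- rec
  out$marks <- marks
  out
}

#' Summarise cardiorespiratory variables over the final window of exercise
#'
#' Peak exercise values are conventionally taken as the mean over the last
#' part of the effort (default 30 s): breaths with time in
#' `[exercise_end - window, exercise_end)` are averaged per channel. VO2 is
#' reported both absolute (L·min⁻¹) and normalised to body mass
#' (mL·kg⁻¹·min⁻¹), alongside the mean respiratory exchange ratio
#' (VCO2/VO2).
#'
#' @param series A `breath_series`.
#' @param window Window length in seconds; must not exceed the exercise
#'   duration.
#' @return A one-row tibble with `n_breaths`, `vo2_l_min`,
#'   `vo2_ml_kg_min`, `vco2_ml_min`, `ve_l_min`, `fr_bpm`, `vt_l`,
#'   `hr_bpm`, `rer`.
#' @export
final_window_summary <- function(series, window = 30) {
  stopifnot(inherits(series, "breath_series"))
  m <- series$marks
  dur <- m$exercise_end - m$exercise_start
  if (window <= 0 || window > dur) {
    abort(sprintf("window must lie in (0, %g] s (exercise duration)", dur))
  }
  rec <- series$records
  keep <- rec$time >= (m$exercise_end - window) & rec$time < m$exercise_end
  if (!any(keep)) {
    abort("no breaths in the final window; widen the window")
  }
  rec <- rec[keep, , drop = FALSE]
  mu <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  vo2 <- mu(rec$vo2)
  vco2 <- mu(rec$vco2)
  tibble(
    n_breaths = nrow(rec),
    vo2_l_min = vo2 / 1000,
    vo2_ml_kg_min = vo2 / series$body_mass,
    vco2_ml_min = vco2,
    ve_l_min = mu(rec$ve),
    fr_bpm = mu(rec$fr),
    vt_l = mu(rec$vt),
    hr_bpm = mu(rec$hr),
    rer = if (is.na(vco2) || vo2 <= 0) NA_real_ else vco2 / vo2
  )
}
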