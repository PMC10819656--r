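# Breath editing: artifact exclusion, +/- k SD retention, breath moving
# average, fixed-width temporal binning. The chain never adds breaths and
# never reorders time.

new_cleaning_report <- function(n_input, n_artifact_removed, n_sd_removed) {
  n_retained <- n_input - n_artifact_removed - n_sd_removed
  structure(
    list(
      n_input = as.integer(n_input),
      n_artifact_removed = as.integer(n_artifact_removed),
      n_sd_removed = as.integer(n_sd_removed),
      n_retained = as.integer(n_retained),
      retained_fraction = if (n_input > 0) n_retained / n_input else NA_real_
    ),
    class = "cleaning_report"
  )
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %d breaths in; %d artifact, %d outlier removed; %d retained (%.1f%%)\n",
    x$n_input, x$n_artifact_removed, x$n_sd_removed, x$n_retained,
    100 * x$retained_fraction
  ))
  invisible(x)
}

#' Remove artifact-flagged breaths
#'
#' Drops every breath whose `artifact` flag is set (coughs, signal
#' interruptions — annotated by the operator or injected by the simulator;
#' the package does not auto-detect them).
#'
#' @param series A `breath_series`.
#' @return A list with `series` (flagged breaths removed) and `report`
#'   (a cleaning report counting the removals).
#' @export
drop_flagged <- function(series) {
  stopifnot(inherits(series, "breath_series"))
  flagged <- series$records$artifact
  out <- series
  out$records <- series$records[!flagged, , drop = FALSE]
  list(
    series = out,
    report = new_cleaning_report(length(flagged), sum(flagged), 0L)
  )
}

#' Retain breaths within mean ± k standard deviations of VO2
#'
#' A single, non-iterated retention pass: the mean and SD of VO2 are
#' computed once per scope on the input, and breaths whose VO2 falls
#' outside `[mean - k*SD, mean + k*SD]` are removed whole (all channels).
#'
#' The default scope is the whole session: the band then spans the full
#' dynamic range of the recording and removes only egregious errant
#' breaths, which is the role of a retention rule applied before model
#' fitting. A per-phase scope (`scope = "phase"`) is also available, but
#' note that within a transient phase the kinetics curve itself spans more
#' than three SDs of the phase distribution, so a per-phase band
#' systematically deletes the early-transient breaths — it distorts rather
#' than denoises (see the package vignette).
#'
#' @param series A `breath_series`.
#' @param k SD multiplier (default 3).
#' @param scope `"session"` (default) or `"phase"`.
#' @return A list with `series` and `report`. A degenerate scope (SD = 0)
#'   removes nothing.
#' @export
sd3_filter <- function(series, k = 3, scope = c("session", "phase")) {
  stopifnot(inherits(series, "breath_series"), k > 0)
  scope <- match.arg(scope)
  rec <- series$records
  n <- nrow(rec)
  keep <- rep(TRUE, n)
  groups <- if (scope == "session") {
    list(seq_len(n))
  } else {
    lapply(c("baseline", "exercise", "recovery"), function(ph) {
      b <- phase_bounds(series$marks, ph)
      which(rec$time >= b[1] & rec$time < b[2])
    })
  }
  for (idx in groups) {
    if (length(idx) < 3) next
    v <- rec$vo2[idx]
    mu <- mean(v)
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) next
    keep[idx] <- v >= mu - k * s & v <= mu + k * s
  }
  out <- series
  out$records <- rec[keep, , drop = FALSE]
  list(
    series = out,
    report = new_cleaning_report(n, 0L, sum(!keep))
  )
}

#' Centred moving average over breaths
#'
#' Replaces each breath's numeric channels by the centred mean over a
#' window of `window_breaths` breaths. The average is computed within each
#' phase separately, with the window shrinking to the available breaths at
#' phase edges: smoothing across a phase boundary would blur the very
#' transition the kinetics models describe (baseline breaths would leak
#' into the early exercise transient). Output length and times equal the
#' input's.
#'
#' @param series A `breath_series`.
#' @param window_breaths Window width in breaths (default 3).
#' @return A smoothed `breath_series`.
#' @export
moving_average <- function(series, window_breaths = 3) {
  stopifnot(inherits(series, "breath_series"), window_breaths >= 1)
  out <- series
  rec <- series$records
  if (nrow(rec) == 0) return(out)
  for (ph in c("baseline", "exercise", "recovery")) {
    b <- phase_bounds(series$marks, ph)
    idx <- which(rec$time >= b[1] & rec$time < b[2])
    if (length(idx) == 0) next
    for (ch in .breath_channels) {
      rec[[ch]][idx] <- as.numeric(zoo::rollapply(
        zoo::zoo(rec[[ch]][idx]), width = window_breaths,
        FUN = function(v) mean(v, na.rm = TRUE),
        align = "center", partial = TRUE
      ))
    }
  }
  out$records <- rec
  out
}

#' Temporal binning of a breath series
#'
#' Groups breaths into consecutive half-open bins of fixed width (default
#' 10 s), anchored at each phase start so bins never straddle a phase
#' boundary. Each non-empty bin emits a single sample at the bin midpoint
#' whose channels are the means of its member breaths; empty bins are
#' omitted. The binned output is itself a `breath_series` and feeds the
#' kinetics fits and integrals unchanged.
#'
#' @param series A `breath_series`.
#' @param width Bin width in seconds (> 0, default 10).
#' @return A `breath_series` of bin-mean samples.
#' @export
time_bin <- function(series, width = 10) {
  stopifnot(inherits(series, "breath_series"), width > 0)
  rec <- series$records
  pieces <- lapply(c("baseline", "exercise", "recovery"), function(ph) {
    b <- phase_bounds(series$marks, ph)
    r <- rec[rec$time >= b[1] & rec$time < b[2], , drop = FALSE]
    if (nrow(r) == 0) return(NULL)
    bin <- floor((r$time - b[1]) / width)
    agg <- lapply(split(seq_len(nrow(r)), bin), function(ix) {
      row <- lapply(r[ix, .breath_channels], function(v) {
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      })
      c(list(time = b[1] + (bin[ix[1]] + 0.5) * width), row)
    })
    dplyr::bind_rows(agg)
  })
  binned <- dplyr::bind_rows(pieces)
  binned <- binned[order(binned$time), , drop = FALSE]
  binned$artifact <- FALSE
  out <- series
  out$records <- as_tibble(binned)
  validate_breath_series(out)
}

#' Full breath-editing chain
#'
#' Applies, in order: artifact exclusion ([drop_flagged()]), the mean ± k SD
#' retention band ([sd3_filter()]), the centred breath moving average
#' ([moving_average()]) and temporal binning ([time_bin()]). The chain is a
#' denoiser: on clean synthetic data it leaves fitted kinetics essentially
#' unchanged.
#'
#' @param series A `breath_series`.
#' @param sd_k SD multiplier for the retention band.
#' @param sd_scope `"session"` (default) or `"phase"`.
#' @param ma_breaths Moving-average window, in breaths.
#' @param bin_s Temporal-bin width in seconds; `NULL` or `0` skips binning.
#' @return A list with `series` (cleaned) and `report` (combined counts over
#'   the two removal stages).
#' @export
clean_breaths <- function(series, sd_k = 3, sd_scope = "session",
                          ma_breaths = 3, bin_s = 10) {
  s1 <- drop_flagged(series)
  s2 <- sd3_filter(s1$series, k = sd_k, scope = sd_scope)
  s3 <- moving_average(s2$series, window_breaths = ma_breaths)
  out <- if (is.null(bin_s) || bin_s <= 0) s3 else time_bin(s3, width = bin_s)
  list(
    series = out,
    report = new_cleaning_report(
      n_breaths(series),
      s1$report$n_artifact_removed,
      s2$report$n_sd_removed
    )
  )
}
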