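test_that("breath series construction enforces the structural invariants", {
  marks <- phase_marks(0, 60, 180, 600)
  expect_s3_class(
    breath_series(tibble::tibble(time = c(1, 2, 3), vo2 = c(400, 410, 420)),
                  marks, 80),
    "breath_series"
  )
  # non-monotone time names the first offending row
  expect_error(
    breath_series(tibble::tibble(time = c(0, 5, 4), vo2 = c(1, 1, 1)), marks, 80),
    "row 3"
  )
  expect_error(
    breath_series(tibble::tibble(time = 1:3, vo2 = c(400, -1, 420)), marks, 80),
    "non-negative"
  )
  expect_error(
    breath_series(tibble::tibble(time = 1:3, vo2 = rep(1, 3)), marks, 0),
    "body_mass"
  )
  expect_error(phase_marks(0, 180, 60, 600), "strictly increasing")
})

test_that("phase slicing uses half-open windows and partitions the records", {
  marks <- phase_marks(0, 60, 180, 600)
  s <- breath_series(
    tibble::tibble(time = c(10, 70, 200), vo2 = c(500, 3000, 800)),
    marks, 80
  )
  ex <- slice_phase(s, "exercise")
  expect_equal(ex$records$time, 70)

  # boundary breath belongs to the later phase
  s2 <- breath_series(tibble::tibble(time = c(59, 60, 179, 180), vo2 = rep(1, 4)),
                      marks, 80)
  expect_equal(slice_phase(s2, "baseline")$records$time, 59)
  expect_equal(slice_phase(s2, "exercise")$records$time, c(60, 179))
  expect_equal(slice_phase(s2, "recovery")$records$time, 180)

  # partition property on a random synthetic series
  spec <- cohort_spec(n = 1, master_seed = 3)
  gen <- generate_cohort(spec)[[1]]$series
  slices <- lapply(c("baseline", "exercise", "recovery"),
                   function(p) slice_phase(gen, p)$records$time)
  expect_equal(sum(lengths(slices)), n_breaths(gen))
  expect_equal(sort(unlist(slices)), gen$records$time)

  expect_warning(
    slice_phase(breath_series(tibble::tibble(time = 10, vo2 = 1), marks, 80),
                "recovery"),
    "no breaths"
  )
})

test_that("final-window summary averages the closing window of exercise", {
  mass <- 87.9
  # constant mass-normalised VO2 of 47.2 over exercise
  p <- kinetics_params(47.2, 0, 0, 1)
  s <- transient_series(p, mass = mass)
  fw <- final_window_summary(s, window = 30)
  expect_equal(fw$vo2_ml_kg_min, 47.2, tolerance = 1e-10)
  expect_equal(fw$vo2_l_min, 47.2 * mass / 1000, tolerance = 1e-10)

  # linear ramp 0 -> 100 over 0 -> 100 s: mean over [70, 100) is 85
  marks <- phase_marks(0, 10, 110, 120)
  tt <- 10 + seq(0.5, 99.5, by = 1)
  ramp <- breath_series(tibble::tibble(time = tt, vo2 = (tt - 10) * mass),
                        marks, mass)
  expect_equal(final_window_summary(ramp, 30)$vo2_ml_kg_min, 85)

  # window equal to the full exercise duration equals the phase mean
  full <- final_window_summary(ramp, 100)
  expect_equal(full$vo2_ml_kg_min,
               mean(slice_phase(ramp, "exercise")$records$vo2) / mass)

  # invariant to a uniform time translation of the whole session
  shift <- 500
  ramp2 <- breath_series(
    tibble::tibble(time = tt + shift, vo2 = (tt - 10) * mass),
    phase_marks(shift, 10 + shift, 110 + shift, 120 + shift), mass
  )
  expect_equal(final_window_summary(ramp2, 30), final_window_summary(ramp, 30))

  expect_error(final_window_summary(ramp, 200), "window")
})

test_that("breath CSV round-trips through write and read", {
  spec <- cohort_spec(n = 1, master_seed = 17)
  sub <- generate_cohort(spec)[[1]]
  path <- file.path(withr::local_tempdir(), "subject.csv")
  write_breath_csv(sub$series, path, panel = sub$panel)
  back <- read_breath_csv(path)

  expect_equal(back$records, sub$series$records, tolerance = 1e-9)
  expect_equal(unclass(back$marks), unclass(sub$series$marks), tolerance = 1e-9)
  expect_equal(back$body_mass, sub$series$body_mass, tolerance = 1e-9)
  p <- attr(back, "panel")
  expect_equal(p$lactate_baseline, sub$panel$lactate_baseline, tolerance = 1e-9)
  expect_equal(unname(p$lactate_post), unname(sub$panel$lactate_post),
               tolerance = 1e-9)
})

test_that("reading rejects malformed rows and columns informatively", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "s.csv")
  side <- file.path(dir, "s.json")
  jsonlite::write_json(
    list(marks = list(baseline_start = 0, exercise_start = 2,
                      exercise_end = 8, recovery_end = 20),
         body_mass = 80),
    side, auto_unbox = TRUE
  )

  writeLines(c("time_s,vo2_ml_min", "1,400", "3,410", "5,420"), path)
  s <- read_breath_csv(path)
  expect_equal(n_breaths(s), 3)
  expect_equal(s$records$vo2, c(400, 410, 420))

  # non-monotone time names the offending row
  writeLines(c("time_s,vo2_ml_min", "0,1", "5,1", "4,1"), path)
  expect_error(read_breath_csv(path), "row 3")

  # non-numeric rows are dropped with their numbers reported
  writeLines(c("time_s,vo2_ml_min", "1,400", "oops,410", "5,420"), path)
  expect_warning(s2 <- read_breath_csv(path), "rows 2")
  expect_equal(n_breaths(s2), 2)

  # missing required column is named
  writeLines(c("time_s,flow", "1,400"), path)
  expect_error(read_breath_csv(path), "vo2_ml_min")

  # vendor dialect mapping
  writeLines(c("t(sec),VO2", "1,400", "3,410", "5,420"), path)
  s3 <- read_breath_csv(path, dialect = c(time_s = "t(sec)", vo2_ml_min = "VO2"))
  expect_equal(s3$records$vo2, c(400, 410, 420))
})

test_that("metabolic panel validates its ranges", {
  p <- metabolic_panel(1.5, c(`1` = 15, `3` = 19, `5` = 20.7, `7` = 19.8),
                       97.1, 141.8, 6, 18)
  expect_s3_class(p, "metabolic_panel")
  expect_error(
    metabolic_panel(-1, c(`1` = 15), 97, 141, 6, 18), "positive"
  )
  expect_error(
    metabolic_panel(1.5, c(`2` = 15), 97, 141, 6, 18), "minute"
  )
  expect_error(
    metabolic_panel(1.5, c(`1` = 15), 97, 141, 6, 25), "Borg"
  )
})
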