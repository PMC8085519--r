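test_that("task time is the segment window length and is scale-free", {
  seg <- structure(list(t_entry = 1.2, t_end = 7.2), class = "task_segment")
  expect_identical(time_metric(seg), 6)

  s <- minjerk_trial_series(A = 10, duration = 5)
  seg1 <- segment_whole(s)
  expect_equal(time_metric(seg1), 5 + 0.01, tolerance = 0.011)
  # spatial scaling leaves T untouched
  s2 <- kinematic_series(s$t, 10 * s$x, 10 * s$y, 10 * s$z, fs = 100)
  expect_identical(time_metric(segment_whole(s2)), time_metric(seg1))
})

test_that("path length measures the traversed path and scales linearly", {
  t <- seq(0, 2, by = 0.01)
  s <- kinematic_series(t, 5 * t, rep(0, length(t)), rep(1, length(t)),
                        fs = 100)
  d <- sg_derivatives(s, 5)
  expect_equal(path_length(d), 10, tolerance = 0.001 * 10)
  s3 <- kinematic_series(t, 15 * t, rep(0, length(t)), rep(1, length(t)),
                         fs = 100)
  expect_equal(path_length(sg_derivatives(s3, 5)), 3 * path_length(d),
               tolerance = 1e-9)
  # measurement noise inflates the apparent path at minimal smoothing
  clean <- minjerk_trial_series(A = 10, duration = 3)
  noisy <- add_sensor_noise(clean, 0.06, seed = 21)
  expect_gt(path_length(sg_derivatives(noisy, 5)),
            path_length(sg_derivatives(clean, 5)))
})

test_that("peak counting matches construction and handles flat profiles", {
  # single uninterrupted minimum-jerk movement: unimodal speed
  d1 <- sg_derivatives(minjerk_trial_series(A = 10, duration = 2), 5)
  expect_identical(count_peaks(d1), 1L)
  # constant position: flat zero speed, no strict maxima
  t <- seq(0, 1, by = 0.01)
  flat <- kinematic_series(t, rep(1, 101), rep(2, 101), rep(3, 101), fs = 100)
  expect_identical(count_peaks(sg_derivatives(flat, 5)), 0L)
  # two submovements with a pause: 2 dominant peaks above a small
  # prominence floor; the literal zero-floor rule additionally counts
  # the tiny SG boundary-fit ripples at the movement/pause junctions
  d2 <- sg_derivatives(ladder_series(2), 5)
  expect_identical(count_peaks(d2, prominence = 1e-3), 2L)
  expect_gte(count_peaks(d2), 2L)
})

test_that("LDLJ attains the analytic minimum-jerk value and scales away", {
  # closed form: integral jerk^2 = 720 A^2 / T^5, PL = A, so
  # dimensionless jerk = 720 for any amplitude and duration
  base <- minjerk_trial_series(A = 10, duration = 3)
  seg <- segment_whole(base)
  d <- sg_derivatives(seg, 5)
  L0 <- ldlj(d, time_metric(seg), path_length(d))
  expect_equal(L0, -log(720), tolerance = 0.01 * log(720))

  one_ldlj <- function(A, dur) {
    s <- minjerk_trial_series(A = A, duration = dur)
    sg <- segment_whole(s)
    dd <- sg_derivatives(sg, 5)
    ldlj(dd, time_metric(sg), path_length(dd))
  }
  # spatial scale k in {0.5, 2, 10} and temporal scale: < 0.5% drift
  for (k in c(0.5, 2, 10)) {
    expect_lt(abs(one_ldlj(10 * k, 3) - L0) / abs(L0), 0.005)
    expect_lt(abs(one_ldlj(10, 3 * k) - L0) / abs(L0), 0.005)
  }
})

test_that("LDLJ penalizes intermittency and guards the zero-jerk case", {
  lv <- vapply(c(1, 4), function(n) {
    s <- ladder_series(n)
    d <- sg_derivatives(s, 5)
    ldlj(d, s$t[length(s$t)] + 0.01, path_length(d))
  }, numeric(1))
  expect_lt(lv[2], lv[1])
  # hand-built degenerate derivative set: exact zero jerk
  dz <- structure(list(t = seq(0, 1, by = 0.01),
                       jerk = matrix(0, 101, 3)),
                  class = "derivative_set")
  expect_error(ldlj(dz, 1, 10), class = "zero_jerk_error")
  expect_error(ldlj(sg_derivatives(minjerk_trial_series(), 5), -1, 10),
               class = "validation_error")
})

test_that("SPARC is amplitude-invariant, bounded by -1, and ladder-monotone", {
  s <- ladder_series(2)
  d <- sg_derivatives(s, 5)
  s_scaled <- kinematic_series(s$t, 7 * s$x, 7 * s$y, 7 * s$z, fs = 100)
  expect_equal(sparc(sg_derivatives(s_scaled, 5)), sparc(d),
               tolerance = 1e-12)
  # -1 is the arc length of a flat unit band alone; any real spectrum
  # adds amplitude variation on top
  for (n in c(1, 2, 8)) {
    sp <- sparc(sg_derivatives(ladder_series(n), 5))
    expect_lt(sp, -1)
  }
  expect_lt(sparc(sg_derivatives(ladder_series(8), 5)),
            sparc(sg_derivatives(ladder_series(1), 5)))
  # identically zero speed is undefined
  t <- seq(0, 1, by = 0.01)
  expect_error(sparc(rep(0, 101), fs = 100), class = "zero_speed_error")
  expect_error(sparc(numeric(1), fs = 100), class = "validation_error")
})

test_that("flash ratio follows its defining arithmetic", {
  seg <- structure(list(
    t_entry = 0, t_end = 6, t_flash = 2,
    flash_intervals = cbind(begin = c(2, 4), end = c(3, 5))),
    class = "task_segment")
  expect_identical(flash_ratio(seg), 0.5)
  none <- structure(list(t_entry = 0, t_end = 6, t_flash = NA_real_,
                         flash_intervals = cbind(begin = numeric(0),
                                                 end = numeric(0))),
                    class = "task_segment")
  expect_identical(flash_ratio(none), 0)
  degen <- seg; degen$t_end <- 2
  degen$flash_intervals <- cbind(begin = 2, end = 2)
  expect_error(flash_ratio(degen), class = "degenerate_trial_error")
})

test_that("the per-trial sweep emits one row per span with shared FR", {
  co <- simulate_cohort(cohort_spec(n_participants = 1,
                                    trials_per_participant = 2),
                        seed = 8)
  tr <- co$trials[[1]]
  rows <- compute_trial_metrics(tr, spans = c(5, 25, 51, 101, 201))
  expect_identical(nrow(rows), 5L)
  expect_identical(length(unique(rows$FR)), 1L)
  expect_true(all(rows$FR >= 0 & rows$FR <= 1))
  ok <- is.na(rows$excluded)
  expect_true(all(rows$T_s[ok] > 0))
  expect_true(all(rows$PL_mm[ok] > 0))
  expect_true(all(rows$Pks[ok] >= 0))
  expect_true(all(rows$SPARC[ok] < 0))
  expect_true(all(is.finite(rows$LDLJ[ok])))

  # a short trial is flagged missing at long spans, not raised
  short <- minjerk_trial_series(A = 5, duration = 1, z0 = 1)
  meta <- trial_meta("P1", "T1", 1, skin_z = 0.999999)
  strial <- structure(list(series = short, meta = meta),
                      class = "cannula_trial")
  srows <- compute_trial_metrics(strial, spans = c(5, 201))
  expect_true(is.na(srows$LDLJ[srows$window_span == 201]))
  expect_match(srows$excluded[srows$window_span == 201], "span")
  expect_false(is.na(srows$LDLJ[srows$window_span == 5]))
})

test_that("cohort-level computation logs unusable trials and continues", {
  co <- simulate_cohort(cohort_spec(n_participants = 2,
                                    trials_per_participant = 2),
                        seed = 8)
  # sabotage one trial: needle never crosses the skin
  bad <- co$trials[[2]]
  bad$series$z <- abs(bad$series$z) + 1
  co$trials[[2]] <- bad
  m <- compute_metrics(co, spans = c(5, 25))
  expect_identical(nrow(m), 3L * 2L)
  excl <- attr(m, "exclusions")
  expect_identical(nrow(excl), 1L)
  expect_identical(excl$trial_id, bad$meta$trial_id)
  expect_true(all(m$FR >= 0 & m$FR <= 1))
})
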