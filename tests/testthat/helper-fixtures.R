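# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# A pure minimum-jerk insertion: starts at z0, descends by A, crossing
# z = skin height almost immediately, so the segmented window covers the
# whole movement.
minjerk_trial_series <- function(A = 10, duration = 2, fs = 100, z0 = 10) {
  mj <- min_jerk_trajectory(c(0, 0, z0), c(0, 0, z0 - A), duration, fs)
  kinematic_series(mj$t, mj$pos[, 1], mj$pos[, 2], mj$pos[, 3], fs = fs)
}

# Ladder of 1..n equal submovements at fixed total displacement (10 mm)
# and fixed per-ladder movement time (4 s split evenly), 0.3 s pauses.
ladder_series <- function(n, fs = 100) {
  dur <- 4 / n
  starts <- seq(0.2, by = dur + 0.3, length.out = n)
  disp <- matrix(rep(c(10 / n, 0, 0), n), ncol = 3, byrow = TRUE)
  compose_trial(submovement_plan(starts, rep(dur, n), disp), fs = fs,
                total_time = starts[n] + dur + 0.3)
}

# closed-form squared-jerk integral of a ladder (pauses contribute zero)
ladder_jerk_integral <- function(n) n * 720 * (10 / n)^2 / (4 / n)^5

segment_whole <- function(series) {
  # segment at a skin height fractionally below the starting z so the
  # full record is retained
  segment_task(series, series$z[1] - 1e-9)
}

# memoised study-scale cohort + metrics shared by the acceptance tests
.acc_cache <- new.env(parent = emptyenv())

acc_cohort <- function() {
  if (is.null(.acc_cache$cohort))
    .acc_cache$cohort <- simulate_cohort(cohort_spec(n_participants = 50),
                                         seed = 11)
  .acc_cache$cohort
}

acc_metrics <- function() {
  if (is.null(.acc_cache$metrics))
    .acc_cache$metrics <- compute_metrics(acc_cohort())
  .acc_cache$metrics
}

acc_metrics_skill <- function() {
  co <- acc_cohort()
  merge(acc_metrics(), co$participants[, c("participant_id", "skill")],
        by = "participant_id")
}
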