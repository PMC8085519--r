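#' Minimum-jerk point-to-point trajectory
#'
#' The canonical maximally smooth reference movement: a quintic
#' p(tau) = p0 + (p1 - p0) (10 tau^3 - 15 tau^4 + 6 tau^5) with zero
#' boundary velocity and acceleration. Its integrated squared jerk is
#' 720 |p1 - p0|^2 / T^5, the analytic anchor used to validate the
#' smoothness metrics, and its peak speed is 1.875 |p1 - p0| / T at the
#' midpoint.
#'
#' @param p0,p1 start and end positions (numeric vectors, mm; any
#'   dimension, typically 3).
#' @param duration movement duration (s), > 0.
#' @param fs sampling rate (Hz); `fs * duration` must be >= 10 samples.
#' @return list with `t` (seconds from 0) and `pos` (matrix, one column
#'   per coordinate).
#' @examples
#' mj <- min_jerk_trajectory(0, 1, duration = 1, fs = 100)
#' max(rowSums(as.matrix(mj$pos)))  # reaches 1 exactly at the end
#' @export
min_jerk_trajectory <- function(p0, p1, duration, fs = 100) {
  if (!is.numeric(duration) || duration <= 0)
    .stopf("duration must be > 0", class = "validation_error")
  if (length(p0) != length(p1))
    .stopf("p0 and p1 must have equal dimension", class = "validation_error")
  if (fs * duration < 10)
    .stopf("need fs * duration >= 10 samples, got %.1f", fs * duration,
           class = "validation_error")
  t <- seq(0, duration, by = 1 / fs)
  tau <- t / duration
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  pos <- outer(rep(1, length(t)), as.numeric(p0)) +
    outer(s, as.numeric(p1) - as.numeric(p0))
  list(t = t, pos = pos)
}

#' Submovement plan for an intermittent needle motion
#'
#' A sequence of non-overlapping minimum-jerk segments separated by
#' stationary pauses. Intermittency (more submovements, longer pauses)
#' is the kinematic signature of lower skill that the smoothness metrics
#' are designed to detect.
#'
#' @param starts segment start times (s), strictly increasing.
#' @param durations segment durations (s), all > 0.
#' @param displacements matrix (one row per segment) of 3-D displacement
#'   vectors (mm).
#' @return An object of class `"submovement_plan"`.
#' @export
submovement_plan <- function(starts, durations, displacements) {
  displacements <- rbind(displacements)
  k <- length(starts)
  if (length(durations) != k || nrow(displacements) != k)
    .stopf("starts, durations, displacements must describe the same number of segments",
           class = "validation_error")
  if (any(durations <= 0))
    .stopf("segment durations must be > 0", class = "validation_error")
  ends <- starts + durations
  if (k > 1 && any(starts[-1] < ends[-k] - 1e-12))
    .stopf("submovement segments must be non-overlapping and ordered",
           class = "validation_error")
  structure(list(starts = as.numeric(starts),
                 durations = as.numeric(durations),
                 displacements = displacements),
            class = "submovement_plan")
}

#' Compose a trial trajectory from a submovement plan
#'
#' Concatenates minimum-jerk segments and exactly stationary pauses;
#' position is continuous at every junction and constant during pauses
#' (no tremor model, so peak counts on noise-free trials are exact).
#'
#' @param plan a [submovement_plan()].
#' @param fs sampling rate (Hz).
#' @param p0 initial 3-D position (mm).
#' @param total_time optional total record length (s); must be >= the end
#'   of the last segment. The trailing interval is a stationary hold.
#' @return A [kinematic_series()] (flash all zeros).
#' @export
compose_trial <- function(plan, fs = 100, p0 = c(0, 0, 0), total_time = NULL) {
  stopifnot(inherits(plan, "submovement_plan"))
  ends <- plan$starts + plan$durations
  t_last <- max(ends)
  if (is.null(total_time)) total_time <- t_last
  if (total_time < t_last - 1e-12)
    .stopf("total_time %.3f s ends before the last segment (%.3f s)",
           total_time, t_last, class = "validation_error")
  t <- seq(0, total_time, by = 1 / fs)
  pos <- outer(rep(1, length(t)), as.numeric(p0))
  for (k in seq_along(plan$starts)) {
    tau <- (t - plan$starts[k]) / plan$durations[k]
    tau <- pmin(pmax(tau, 0), 1)
    s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    pos <- pos + outer(s, plan$displacements[k, ])
  }
  kinematic_series(t, pos[, 1], pos[, 2], pos[, 3], fs = fs)
}

# mean absolute value of the strict local extrema of a vector
.extrema_mean <- function(v) {
  d <- diff(v)
  idx <- which(diff(sign(d)) != 0) + 1L
  if (!length(idx)) return(NA_real_)
  mean(abs(v[idx]))
}

#' Add band-limited sensor noise calibrated by its local-extrema mean
#'
#' Electromagnetic-tracker noise is emulated as white Gaussian noise
#' low-pass filtered to `bandwidth` (4th-order zero-phase Butterworth),
#' then scaled per axis so that the mean absolute value of the noise
#' process's local extrema equals `peak_mean` -- the one calibration
#' statistic available for the real sensor (peaks averaging 0.06 mm).
#' The spectrum below the cutoff is otherwise flat; only the extrema
#' statistic is treated as known.
#'
#' @param series a [kinematic_series()].
#' @param peak_mean target mean absolute local-extremum amplitude (mm);
#'   0 returns the input unchanged.
#' @param bandwidth noise bandwidth (Hz), default 15.
#' @param seed RNG seed; a fixed seed makes the output deterministic.
#' @return A [kinematic_series()] with noisy x, y, z (t, flash, fs
#'   untouched).
#' @export
add_sensor_noise <- function(series, peak_mean = 0.06, bandwidth = 15,
                             seed = NULL) {
  stopifnot(inherits(series, "kinematic_series"))
  if (peak_mean < 0)
    .stopf("peak_mean must be >= 0", class = "validation_error")
  if (peak_mean == 0) return(series)
  n <- length(series$t)
  bf <- signal::butter(4, min(bandwidth / (series$fs / 2), 0.99))
  noisy <- .with_seed(seed, {
    lapply(c("x", "y", "z"), function(ax) {
      w <- stats::rnorm(n)
      nz <- signal::filtfilt(bf, w)
      em <- .extrema_mean(nz)
      if (is.na(em) || em == 0) nz <- numeric(n) else nz <- nz * (peak_mean / em)
      series[[ax]] + nz
    })
  })
  kinematic_series(series$t, noisy[[1]], noisy[[2]], noisy[[3]],
                   series$flash, fs = series$fs)
}

#' Simulate the flashback LED channel for a trial
#'
#' Flashback (the in-needle LED standing in for blood return) switches on
#' a skill-dependent delay after the needle first drops below the skin
#' surface, then runs in fixed blocks each of which is extinguished
#' independently with probability `interrupt_max * (1 - skill)`. Higher
#' skill therefore yields a stochastically higher flash ratio; skill = 1
#' gives an uninterrupted flash from onset to the end of the record.
#'
#' @param series a [kinematic_series()] whose z channel crosses below
#'   `skin_z`.
#' @param skin_z skin-surface height (mm).
#' @param skill latent skill scalar in `[0, 1]`.
#' @param onset_delay_max maximum onset delay (s) at skill 0.
#' @param interrupt_max per-block interruption probability at skill 0.
#' @param block_len flash block length (s).
#' @param seed RNG seed.
#' @return The series with its `flash` channel replaced (all zeros when
#'   the needle never crosses the skin or every block is interrupted).
#' @export
simulate_flash <- function(series, skin_z, skill,
                           onset_delay_max = 0.5, interrupt_max = 0.6,
                           block_len = 0.5, seed = NULL) {
  stopifnot(inherits(series, "kinematic_series"))
  if (skill < 0 || skill > 1)
    .stopf("skill must lie in [0, 1]", class = "validation_error")
  n <- length(series$t)
  entry_idx <- which(series$z < skin_z)[1]
  flash <- .with_seed(seed, {
    fl <- numeric(n)
    if (!is.na(entry_idx)) {
      delay <- stats::runif(1, 0, onset_delay_max) * (1 - skill)
      onset <- series$t[entry_idx] + delay
      on_idx <- which(series$t >= onset)
      if (length(on_idx)) {
        p_int <- min(1, max(0, interrupt_max * (1 - skill)))
        block <- floor((series$t[on_idx] - onset) / block_len)
        keep <- stats::runif(max(block) + 1L) >= p_int
        fl[on_idx] <- as.numeric(keep[block + 1L])
      }
    }
    fl
  })
  kinematic_series(series$t, series$x, series$y, series$z, flash,
                   fs = series$fs)
}

#' Specification of a synthetic cannulation cohort
#'
#' Defaults reproduce the study design the analysis assumes: 52
#' participants each performing 4 attempts on each of 4 fistulas (16
#' trials), kinematics sampled at 100 Hz with sensor-noise peaks
#' averaging 0.06 mm. A single latent skill scalar per participant
#' drives, monotonically, the number and pacing of submovements, flash
#' interruptions, the expert GRS rating (with rater noise), and --
#' weakly, by design -- years of experience.
#'
#' @param n_participants number of participants (default 52).
#' @param trials_per_participant trials each (default 16).
#' @param fs sampling rate, Hz (default 100).
#' @param skill_mean,skill_sd latent skill distribution (normal,
#'   truncated to `[0, 1]`).
#' @param noise_peak_mean sensor-noise calibration (mm), see
#'   [add_sensor_noise()]. This is the cohort-wide mean peak level; each
#'   trial's own level is drawn around it (see `noise_peak_cv`).
#' @param noise_peak_cv coefficient of variation of the per-trial noise
#'   amplitude (lognormal with mean `noise_peak_mean`; default 0.3),
#'   emulating session-to-session variation of electromagnetic-tracker
#'   noise (distance to transmitter, interference). 0 gives every trial
#'   the identical level.
#' @param noise_bandwidth noise bandwidth (Hz).
#' @param effect_map named list of skill-effect coefficients:
#'   `submovement_rate` (Poisson mean of extra submovements at
#'   performance 0), `pause_scale` (mean pause duration, s, at
#'   performance 0), `flash_interrupt_max` (per-block interruption
#'   probability at performance 0), `flash_delay_max` (max flash onset
#'   delay, s), `trial_skill_sd` (sd of the per-trial performance
#'   scalar around participant skill -- both the kinematic
#'   intermittency and the flashback of one trial are driven by the
#'   same realized performance, so the outcome metric shares
#'   trial-level variance with the process metrics), `grs_noise_sd`
#'   (rater noise per subscore on the 1-7 scale), `exp_skill_weight`
#'   (correlation weight of experience with skill; 0 decouples them).
#' @param skin_z skin-surface height (mm).
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_participants = 52, trials_per_participant = 16,
                        fs = 100, skill_mean = 0.7, skill_sd = 0.2,
                        noise_peak_mean = 0.06, noise_peak_cv = 0.3,
                        noise_bandwidth = 15,
                        effect_map = list(), skin_z = 0) {
  em <- utils::modifyList(
    list(submovement_rate = 6, pause_scale = 0.5,
         flash_interrupt_max = 0.6, flash_delay_max = 0.5,
         trial_skill_sd = 0.2, grs_noise_sd = 2.0,
         exp_skill_weight = 0.1),
    effect_map)
  if (!.is_count(trials_per_participant))
    .stopf("trials_per_participant must be a positive integer",
           class = "validation_error")
  if (noise_peak_mean < 0 || noise_peak_cv < 0)
    .stopf("noise_peak_mean and noise_peak_cv must be >= 0",
           class = "validation_error")
  probs <- c(em$flash_interrupt_max)
  if (any(probs < 0 | probs > 1))
    .stopf("probabilities in effect_map must lie in [0, 1]",
           class = "validation_error")
  structure(list(n_participants = n_participants,
                 trials_per_participant = trials_per_participant,
                 fs = fs, skill_mean = skill_mean, skill_sd = skill_sd,
                 noise_peak_mean = noise_peak_mean,
                 noise_peak_cv = noise_peak_cv,
                 noise_bandwidth = noise_bandwidth,
                 effect_map = em, skin_z = skin_z),
            class = "cohort_spec")
}

# one trial's kinematics + flash for a given participant skill.
# Geometry: approach from 15 mm above the skin to 8 mm below (into the
# fistula), skill-dependent corrective submovements below the skin, a
# levelling movement, then a stationary hold so every trial retains a
# usable post-entry record.
.simulate_trial_series <- function(spec, skill) {
  em <- spec$effect_map
  start <- c(stats::runif(1, -5, 5), stats::runif(1, -5, 5), spec$skin_z + 15)
  starts <- 0.2
  durs <- stats::runif(1, 1.2, 1.8)
  disps <- rbind(c(stats::rnorm(1, 0, 1), stats::rnorm(1, 0, 1), -23))
  t_cur <- starts + durs
  depth <- -8                      # z relative to skin after approach
  n_extra <- stats::rpois(1, em$submovement_rate * (1 - skill))
  for (i in seq_len(n_extra)) {
    pause <- stats::rexp(1, 1 / (em$pause_scale * (1 - skill) + 0.05))
    t_cur <- t_cur + pause
    dz <- stats::rnorm(1, 0, 1.2)
    dz <- max(min(dz, -2 - depth), -6 - depth)   # stay 2..6 mm below skin
    depth <- depth + dz
    d <- c(stats::rnorm(1, 0, 1.5), stats::rnorm(1, 0, 1.5), dz)
    dur <- stats::runif(1, 0.2, 0.45)   # corrective jabs are brisk
    starts <- c(starts, t_cur); durs <- c(durs, dur)
    disps <- rbind(disps, d)
    t_cur <- t_cur + dur
  }
  # levelling out: mostly horizontal glide once flashback is stable
  starts <- c(starts, t_cur + 0.2)
  durs <- c(durs, 1.0)
  disps <- rbind(disps, c(5, 0, 1))
  t_cur <- t_cur + 0.2 + 1.0
  plan <- submovement_plan(starts, durs, disps)
  compose_trial(plan, fs = spec$fs, p0 = start, total_time = t_cur + 1.5)
}

#' Simulate a full synthetic cohort
#'
#' Latent skill is drawn once per participant; every kinematic and
#' indicator effect is a monotone function of it. GRS subscores are
#' discretized noisy skill on the 1-7 scale; experience is generated with
#' the (configurably weak) skill correlation `exp_skill_weight`. The
#' cohort is a pure function of `(spec, seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer RNG seed.
#' @return An object of class `"cannula_cohort"`: list with `trials`
#'   (list of `"cannula_trial"`), `participants` (data.frame incl. the
#'   latent `skill` ground truth), `spec`, `seed`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  em <- spec$effect_map
  .with_seed(seed, {
    np <- spec$n_participants
    skill <- pmin(pmax(stats::rnorm(np, spec$skill_mean, spec$skill_sd), 0), 1)
    pid <- sprintf("P%03d", seq_len(np))
    # experience: weakly coupled to skill, clinic-realistic scale 0..38 y
    zskill <- as.numeric(scale(skill))
    if (any(!is.finite(zskill))) zskill <- rep(0, np)
    w <- em$exp_skill_weight
    e_lat <- w * zskill + sqrt(max(0, 1 - w^2)) * stats::rnorm(np)
    years <- pmin(pmax(round(11 + 8.6 * e_lat), 0), 38)
    grs_names <- c("palpation", "needle_holding", "needle_movement",
                   "flashback_quality", "overall_quality")
    grs <- do.call(cbind, lapply(grs_names, function(nm)
      pmin(pmax(round(1 + 6 * skill + stats::rnorm(np, 0, em$grs_noise_sd)), 1), 7)))
    colnames(grs) <- grs_names
    participants <- data.frame(participant_id = pid, skill = skill,
                               years_experience = years,
                               stats::setNames(as.data.frame(grs),
                                               paste0("grs_", grs_names)),
                               stringsAsFactors = FALSE)
    trials <- vector("list", np * spec$trials_per_participant)
    k <- 0L
    for (i in seq_len(np)) {
      for (j in seq_len(spec$trials_per_participant)) {
        perf <- min(max(skill[i] + stats::rnorm(1, 0, em$trial_skill_sd), 0), 1)
        series <- .simulate_trial_series(spec, perf)
        if (spec$noise_peak_mean > 0) {
          cv <- spec$noise_peak_cv
          peak <- if (cv > 0) {
            sdlog <- sqrt(log(1 + cv^2))
            spec$noise_peak_mean * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
          } else spec$noise_peak_mean
          series <- add_sensor_noise(series, peak,
                                     spec$noise_bandwidth, seed = NULL)
        }
        series <- simulate_flash(series, spec$skin_z, perf,
                                 onset_delay_max = em$flash_delay_max,
                                 interrupt_max = em$flash_interrupt_max,
                                 seed = NULL)
        meta <- trial_meta(participant_id = pid[i],
                           trial_id = sprintf("%s_T%02d", pid[i], j),
                           fistula_id = ((j - 1L) %/% 4L) %% 4L + 1L,
                           skin_z = spec$skin_z, fs = spec$fs,
                           years_experience = years[i],
                           grs = stats::setNames(grs[i, ], grs_names))
        k <- k + 1L
        trials[[k]] <- structure(list(series = series, meta = meta),
                                 class = "cannula_trial")
      }
    }
    structure(list(trials = trials, participants = participants,
                   spec = spec, seed = seed),
              class = "cannula_cohort")
  })
}

#' @export
print.cannula_cohort <- function(x, ...) {
  cat(sprintf("<cannula_cohort> %d participants x %d trials (%d total), seed %s\n",
              x$spec$n_participants, x$spec$trials_per_participant,
              length(x$trials), format(x$seed)))
  invisible(x)
}

#' Write a cohort to a trial directory
#'
#' Emits one CSV + JSON sidecar per trial, a `participants.csv` with the
#' participant-level indicators, a `latent_skill.csv` holding the
#' synthetic ground-truth skill (which has no real-data counterpart),
#' and a `manifest.json` with the seed and per-file MD5 checksums.
#'
#' @param cohort a `"cannula_cohort"`.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cannula_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tr in cohort$trials) write_trial(tr, dir)
  p <- cohort$participants
  utils::write.csv(p[, setdiff(names(p), "skill")],
                   file.path(dir, "participants.csv"), row.names = FALSE)
  utils::write.csv(data.frame(participant_id = p$participant_id,
                              skill = .fmt_num(p$skill)),
                   file.path(dir, "latent_skill.csv"), row.names = FALSE)
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  manifest <- list(seed = cohort$seed,
                   n_trials = length(cohort$trials),
                   md5 = as.list(tools::md5sum(file.path(dir, files))))
  names(manifest$md5) <- files
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir directory containing trial CSV/JSON pairs and
#'   `participants.csv`.
#' @return A `"cannula_cohort"` (latent skill included only if
#'   `latent_skill.csv` is present).
#' @export
read_cohort <- function(dir) {
  csvs <- sort(setdiff(list.files(dir, pattern = "\\.csv$", full.names = TRUE),
                       file.path(dir, c("participants.csv", "latent_skill.csv"))))
  trials <- lapply(csvs, read_trial)
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  colClasses = c(participant_id = "character"))
  sk <- file.path(dir, "latent_skill.csv")
  if (file.exists(sk)) {
    skill <- utils::read.csv(sk, colClasses = c(participant_id = "character"))
    participants <- merge(skill, participants, by = "participant_id",
                          sort = TRUE)
  }
  structure(list(trials = trials, participants = participants,
                 spec = NULL, seed = NULL),
            class = "cannula_cohort")
}
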