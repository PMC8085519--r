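#' Task time
#'
#' Total time of the constrained task, `T = t_end - t_entry` (s).
#'
#' @param segment a `"task_segment"`.
#' @return numeric scalar, > 0.
#' @export
time_metric <- function(segment) {
  stopifnot(inherits(segment, "task_segment"))
  segment$t_end - segment$t_entry
}

#' Path length
#'
#' Sum of Euclidean distances between consecutive smoothed needle-tip
#' positions over the task window (mm). Computed on the Savitzky-Golay
#' position estimate so that the metric shares a smoothing level with
#' the derivatives.
#'
#' @param dset a `"derivative_set"`.
#' @return numeric scalar (mm).
#' @export
path_length <- function(dset) {
  stopifnot(inherits(dset, "derivative_set"))
  steps <- diff(dset$position)
  sum(sqrt(rowSums(steps^2)))
}

# strict local maxima indices; optional prominence floor.
# Prominence of a peak = height above the higher of the two deepest
# valleys separating it from higher terrain (standard definition).
.find_peaks <- function(v, prominence = 0) {
  d <- diff(v)
  idx <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  if (!length(idx) || prominence <= 0) return(idx)
  keep <- vapply(idx, function(i) {
    h <- v[i]
    left <- v[seq_len(i - 1)]
    hi_l <- which(left > h)
    base_l <- if (length(hi_l)) min(v[(max(hi_l) + 1):(i - 1)]) else min(left)
    right <- v[(i + 1):length(v)]
    hi_r <- which(right > h)
    base_r <- if (length(hi_r)) min(right[seq_len(min(hi_r) - 1)]) else min(right)
    (h - max(base_l, base_r)) >= prominence
  }, logical(1))
  idx[keep]
}

#' Count peaks in the velocity profile
#'
#' Number of strict local maxima of the speed profile exceeding a
#' prominence floor (default 0, i.e. literal local maxima). More peaks
#' indicate more submovements, hence less smooth motion.
#'
#' @param dset a `"derivative_set"`.
#' @param prominence minimum peak prominence (mm/s) for noisy data;
#'   default 0.
#' @return integer count, >= 0.
#' @export
count_peaks <- function(dset, prominence = 0) {
  stopifnot(inherits(dset, "derivative_set"))
  length(.find_peaks(dset$speed, prominence))
}

#' Log dimensionless jerk (LDLJ)
#'
#' The squared magnitude of the 3-D jerk vector is integrated over the
#' task window by the trapezoidal rule, made dimensionless by the factor
#' `T^5 / PL^2`, and the metric is the negated natural log of its
#' absolute value:
#' `LDLJ = -ln| (T^5 / PL^2) * integral( |jerk|^2 dt ) |`.
#' Higher (less negative) values indicate smoother motion; a single
#' noise-free minimum-jerk movement attains the ceiling `-ln(720)`
#' regardless of amplitude or duration.
#'
#' @param dset a `"derivative_set"`.
#' @param T task time (s), from [time_metric()].
#' @param PL path length (mm), from [path_length()].
#' @return numeric scalar (dimensionless, log scale).
#' @section Errors: identically zero jerk (e.g. exactly constant
#'   velocity) makes the log undefined and raises a `zero_jerk_error`.
#' @export
ldlj <- function(dset, T, PL) {
  stopifnot(inherits(dset, "derivative_set"))
  if (T <= 0 || PL <= 0)
    .stopf("T and PL must be positive (T = %g, PL = %g)", T, PL,
           class = "validation_error")
  jerk_sq <- rowSums(dset$jerk^2)
  integral <- pracma::trapz(dset$t, jerk_sq)
  dlj <- (T^5 / PL^2) * integral
  if (dlj == 0)
    .stopf("jerk is identically zero; LDLJ is undefined for this trial",
           class = "zero_jerk_error")
  -log(abs(dlj))
}

#' Spectral arc length (SPARC)
#'
#' Arc length of the frequency-normalized Fourier magnitude spectrum of
#' the speed profile. The speed profile is zero-padded to
#' `2^(ceil(log2 n) + padlevel)` points, its magnitude spectrum is
#' normalized by the DC value `V(0)`, and an adaptive cutoff `omega_c`
#' is chosen as the largest frequency not above `f_max` at which the
#' normalized magnitude still reaches `amp_threshold`. The metric is the
#' negated arc length of the normalized spectrum over `[0, omega_c]`
#' with the frequency axis scaled by `omega_c`:
#' `SPARC = -integral sqrt( (1/omega_c)^2 + (dVhat/domega)^2 ) domega`.
#' It is exactly invariant to amplitude scaling and always below -1 for
#' any nonconstant profile; less negative = smoother. The free
#' parameters default to the metric's published reference values.
#'
#' @param dset a `"derivative_set"`, or a bare numeric speed profile
#'   (then `fs` must be given).
#' @param fs sampling rate (Hz); taken from `dset` when available.
#' @param padlevel zero-padding exponent (default 4).
#' @param f_max maximum cutoff frequency in Hz (default 10).
#' @param amp_threshold normalized amplitude threshold for the adaptive
#'   cutoff (default 0.05).
#' @return numeric scalar, < 0.
#' @section Errors: an identically zero speed profile has `V(0) = 0`
#'   and raises a `zero_speed_error`.
#' @export
sparc <- function(dset, fs = NULL, padlevel = 4, f_max = 10,
                  amp_threshold = 0.05) {
  if (inherits(dset, "derivative_set")) {
    v <- dset$speed
    fs <- dset$fs
  } else {
    v <- as.numeric(dset)
    if (is.null(fs)) .stopf("fs is required with a bare speed profile")
  }
  if (length(v) < 2)
    .stopf("speed profile must have at least 2 samples",
           class = "validation_error")
  if (all(v == 0))
    .stopf("speed profile is identically zero; SPARC is undefined",
           class = "zero_speed_error")
  nfft <- 2^ceiling(log2(length(v)) + padlevel)
  f <- seq(0, fs, length.out = nfft + 1)[1:nfft]
  Mf <- Mod(stats::fft(c(v, numeric(nfft - length(v)))))
  Mf <- Mf / Mf[1]                     # Vhat = V(omega) / V(0)
  sel <- which(f <= f_max)
  above <- which(Mf[sel] >= amp_threshold)
  rng <- above[1]:above[length(above)] # DC is always >= threshold
  f_sel <- f[sel][rng]
  M_sel <- Mf[sel][rng]
  f_range <- f_sel[length(f_sel)] - f_sel[1]   # adaptive cutoff
  -sum(sqrt((diff(f_sel) / f_range)^2 + diff(M_sel)^2))
}

#' Flash ratio (FR)
#'
#' Objective outcome metric: the fraction of the time from the first
#' flashback to the end of the task during which flashback was
#' maintained,
#' `FR = sum(t_flash_end - t_flash_begin) / (t_end - t_flash)`.
#' A trial with no flashback scores 0; uninterrupted flashback from
#' onset to the end scores exactly 1. FR does not depend on the
#' smoothing window span.
#'
#' @param segment a `"task_segment"`.
#' @return numeric scalar in `[0, 1]`.
#' @export
flash_ratio <- function(segment) {
  stopifnot(inherits(segment, "task_segment"))
  iv <- segment$flash_intervals
  if (nrow(iv) == 0L) return(0)
  den <- segment$t_end - segment$t_flash
  if (den <= 0)
    .stopf("degenerate trial: task ends at the first flashback",
           class = "degenerate_trial_error")
  sum(iv[, "end"] - iv[, "begin"]) / den
}

#' Compute all process metrics for one trial across window spans
#'
#' Segments the trial, computes the flash ratio once (span-independent),
#' then sweeps the Savitzky-Golay window spans computing T, PL, Pks,
#' LDLJ and SPARC. A span longer than the segment, or a degenerate
#' metric, yields a row with `NA` metrics and the reason in the
#' `excluded` column rather than an error, mirroring a real study's
#' per-trial exclusion log.
#'
#' @param trial a `"cannula_trial"` (list with `series`, `meta`).
#' @param spans odd window spans in samples (default
#'   `c(5, 25, 51, 101, 201)`).
#' @param sparc_args list of [sparc()] parameter overrides.
#' @param peak_prominence prominence floor for [count_peaks()].
#' @return data.frame with one row per span: `participant_id`,
#'   `trial_id`, `window_span`, `T_s`, `PL_mm`, `Pks`, `LDLJ`, `SPARC`,
#'   `FR`, `excluded`.
#' @export
compute_trial_metrics <- function(trial, spans = c(5, 25, 51, 101, 201),
                                  sparc_args = list(),
                                  peak_prominence = 0) {
  seg <- segment_task(trial$series, trial$meta$skin_z)
  FR <- flash_ratio(seg)
  T <- time_metric(seg)
  rows <- lapply(spans, function(span) {
    res <- tryCatch({
      dset <- sg_derivatives(seg, span)
      PL <- path_length(dset)
      list(T = T, PL = PL, Pks = count_peaks(dset, peak_prominence),
           LDLJ = ldlj(dset, T, PL),
           SPARC = do.call(sparc, c(list(dset), sparc_args)),
           excluded = NA_character_)
    }, cannulaskill_error = function(e) {
      list(T = NA_real_, PL = NA_real_, Pks = NA_integer_,
           LDLJ = NA_real_, SPARC = NA_real_,
           excluded = conditionMessage(e))
    })
    data.frame(participant_id = trial$meta$participant_id,
               trial_id = trial$meta$trial_id,
               window_span = as.integer(span),
               T_s = res$T, PL_mm = res$PL, Pks = res$Pks,
               LDLJ = res$LDLJ, SPARC = res$SPARC, FR = FR,
               excluded = res$excluded, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compute the metrics table for a whole cohort
#'
#' Applies [compute_trial_metrics()] to every trial; trials that fail
#' outright (e.g. no skin entry) are skipped and recorded in the
#' `"exclusions"` attribute with their reason, so the run continues --
#' exclusion is an analysis-layer decision.
#'
#' @param cohort a `"cannula_cohort"` or list of `"cannula_trial"`.
#' @inheritParams compute_trial_metrics
#' @return data.frame of metric rows (see [compute_trial_metrics()]),
#'   with attribute `exclusions` (data.frame `trial_id`, `reason`).
#' @export
compute_metrics <- function(cohort, spans = c(5, 25, 51, 101, 201),
                            sparc_args = list(), peak_prominence = 0) {
  trials <- if (inherits(cohort, "cannula_cohort")) cohort$trials else cohort
  out <- vector("list", length(trials))
  excl <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    res <- tryCatch(
      compute_trial_metrics(tr, spans, sparc_args, peak_prominence),
      cannulaskill_error = function(e) e)
    if (inherits(res, "condition")) {
      excl[[length(excl) + 1L]] <- data.frame(
        trial_id = tr$meta$trial_id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      out[[i]] <- res
    }
  }
  tab <- do.call(rbind, out)
  attr(tab, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(trial_id = character(0), reason = character(0))
  tab
}
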