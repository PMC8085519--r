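#' Construct a validated needle-tip kinematic series
#'
#' The raw unit of analysis: a uniformly sampled 3-D needle-tip trajectory
#' with a synchronous binary flashback channel. Positions are in
#' millimetres (z vertical, larger = higher), time in seconds. The nominal
#' sampling rate is 100 Hz; the median sample interval must lie within 1%
#' of `1/fs`, otherwise the series is rejected (Savitzky-Golay filtering
#' downstream assumes uniform spacing; see [resample_uniform()] for the
#' explicit repair path).
#'
#' @param t numeric vector of timestamps (s), strictly increasing.
#' @param x,y,z numeric position coordinates (mm), same length as `t`.
#' @param flash binary (0/1) flashback indicator per sample; defaults to
#'   all zeros.
#' @param fs nominal sampling rate in Hz (default 100).
#' @return An object of class `"kinematic_series"`: a list with fields
#'   `t`, `x`, `y`, `z`, `flash`, `fs`.
#' @seealso [read_trial()], [segment_task()]
#' @export
kinematic_series <- function(t, x, y, z, flash = NULL, fs = 100) {
  if (is.null(flash)) flash <- numeric(length(t))
  n <- length(t)
  if (n < 2L)
    .stopf("a kinematic series needs at least 2 samples, got %d", n,
           class = "validation_error")
  lens <- c(length(x), length(y), length(z), length(flash))
  if (any(lens != n))
    .stopf("t, x, y, z, flash must have equal length (t has %d)", n,
           class = "validation_error")
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    .stopf("timestamps must be finite and strictly increasing",
           class = "validation_error")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    .stopf("fs must be a positive scalar", class = "validation_error")
  dts <- diff(t)
  if (abs(stats::median(dts) - 1 / fs) > 0.01 / fs ||
      max(abs(dts - 1 / fs)) > 0.01 / fs)
    .stopf("sampling is non-uniform beyond 1%% of 1/fs = %.6g s; resample explicitly with resample_uniform()",
           1 / fs, class = "validation_error")
  if (!all(flash %in% c(0, 1)))
    .stopf("flash channel must be binary (0/1)", class = "validation_error")
  structure(
    list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
         z = as.numeric(z), flash = as.numeric(flash), fs = as.numeric(fs)),
    class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %d samples @ %g Hz, %.2f s, flash on %.0f%% of samples\n",
              length(x$t), x$fs, x$t[length(x$t)] - x$t[1],
              100 * mean(x$flash)))
  invisible(x)
}

#' @export
length.kinematic_series <- function(x) length(x$t)

#' Per-trial metadata
#'
#' Participant/trial identifiers, the skin-surface height used for entry
#' detection, clinical experience, and the five expert global-rating-sheet
#' (GRS) subscores on a 1-7 Likert scale. The palpation subscore is kept
#' in the record but is excluded from the default GRS sum because it does
#' not reflect needle motion; the scoring choice is made at analysis time
#' (see [skill_assoc()]).
#'
#' @param participant_id,trial_id character identifiers.
#' @param fistula_id integer 1..4, which simulated fistula was cannulated.
#' @param skin_z height of the skin surface (mm) in the tracker frame.
#' @param fs sampling rate (Hz) recorded with the trial.
#' @param years_experience non-negative years of cannulation experience.
#' @param grs named numeric vector/list of the five subscores
#'   (`palpation`, `needle_holding`, `needle_movement`,
#'   `flashback_quality`, `overall_quality`), each in 1..7.
#' @return An object of class `"trial_meta"`.
#' @export
trial_meta <- function(participant_id, trial_id, fistula_id, skin_z,
                       fs = 100, years_experience = 0,
                       grs = c(palpation = 4, needle_holding = 4,
                               needle_movement = 4, flashback_quality = 4,
                               overall_quality = 4)) {
  grs <- unlist(grs)
  need <- c("palpation", "needle_holding", "needle_movement",
            "flashback_quality", "overall_quality")
  if (!all(need %in% names(grs)))
    .stopf("grs must contain subscores: %s",
           paste(setdiff(need, names(grs)), collapse = ", "),
           class = "validation_error")
  grs <- stats::setNames(as.numeric(grs[need]), need)
  if (any(grs < 1 | grs > 7))
    .stopf("GRS subscores must lie in [1, 7]", class = "validation_error")
  if (years_experience < 0)
    .stopf("years_experience must be >= 0", class = "validation_error")
  if (!fistula_id %in% 1:4)
    .stopf("fistula_id must be in 1..4", class = "validation_error")
  structure(
    list(participant_id = as.character(participant_id),
         trial_id = as.character(trial_id),
         fistula_id = as.integer(fistula_id),
         skin_z = as.numeric(skin_z),
         fs = as.numeric(fs),
         years_experience = as.numeric(years_experience),
         grs = grs),
    class = "trial_meta")
}

#' Read one trial (kinematics CSV + JSON metadata sidecar)
#'
#' The CSV must have header columns `time_s, x_mm, y_mm, z_mm, flash`;
#' units are fixed in the column names to prevent silent unit drift. The
#' JSON sidecar carries the [trial_meta()] fields.
#'
#' @param csv_path path to the kinematics CSV.
#' @param meta_path path to the JSON sidecar; defaults to `csv_path` with
#'   the extension replaced by `.json`.
#' @return A list with elements `series` ([kinematic_series()]) and
#'   `meta` ([trial_meta()]), of class `"cannula_trial"`.
#' @export
read_trial <- function(csv_path, meta_path = sub("\\.csv$", ".json", csv_path)) {
  dat <- utils::read.csv(csv_path, check.names = FALSE)
  need <- c("time_s", "x_mm", "y_mm", "z_mm", "flash")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    .stopf("trial CSV '%s' is missing column(s): %s", csv_path,
           paste(miss, collapse = ", "), class = "format_error")
  m <- jsonlite::fromJSON(meta_path)
  meta <- trial_meta(participant_id = m$participant_id,
                     trial_id = m$trial_id,
                     fistula_id = m$fistula_id,
                     skin_z = m$skin_z_mm,
                     fs = m$fs_hz,
                     years_experience = m$years_experience,
                     grs = unlist(m$grs))
  series <- kinematic_series(dat$time_s, dat$x_mm, dat$y_mm, dat$z_mm,
                             dat$flash, fs = meta$fs)
  structure(list(series = series, meta = meta), class = "cannula_trial")
}

#' Write one trial to CSV + JSON sidecar
#'
#' Numeric fields are serialized at full double precision so a
#' write/read round trip is bit-exact.
#'
#' @param trial a `"cannula_trial"` (list with `series` and `meta`).
#' @param dir output directory (created if needed).
#' @return Invisibly, the CSV path.
#' @export
write_trial <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- trial$series; m <- trial$meta
  csv_path <- file.path(dir, paste0(m$trial_id, ".csv"))
  out <- data.frame(time_s = .fmt_num(s$t), x_mm = .fmt_num(s$x),
                    y_mm = .fmt_num(s$y), z_mm = .fmt_num(s$z),
                    flash = as.integer(s$flash))
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  meta <- list(participant_id = m$participant_id, trial_id = m$trial_id,
               fistula_id = m$fistula_id, skin_z_mm = m$skin_z,
               fs_hz = m$fs, years_experience = m$years_experience,
               grs = as.list(m$grs))
  jsonlite::write_json(meta, sub("\\.csv$", ".json", csv_path),
                       auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' Write the tidy long-format process-metrics table
#'
#' One row per (trial, window span), sorted by
#' (participant_id, trial_id, window_span); numeric columns at full
#' double precision.
#'
#' @param rows data.frame of metric rows (as produced by
#'   [compute_metrics()]).
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_metrics_table <- function(rows, path) {
  if (is.null(rows) || nrow(rows) == 0L)
    .stopf("refusing to write an empty metrics table", class = "validation_error")
  ord <- order(rows$participant_id, rows$trial_id, rows$window_span)
  rows <- rows[ord, , drop = FALSE]
  out <- rows
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- .fmt_num(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a process-metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return data.frame of metric rows.
#' @export
read_metrics_table <- function(path) {
  dat <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(participant_id = "character",
                                        trial_id = "character"))
  dat
}

#' Resample a kinematic series to a uniform grid
#'
#' Linear interpolation onto a uniform grid at rate `fs`. This is the
#' deliberate repair path for recordings whose jitter exceeds the 1%
#' tolerance of [kinematic_series()]; it is never applied implicitly.
#' The flash channel is resampled by nearest-neighbour (it is binary).
#'
#' @param t,x,y,z,flash raw (possibly non-uniform) channels.
#' @param fs target sampling rate (Hz).
#' @return A [kinematic_series()] at uniform spacing `1/fs`.
#' @export
resample_uniform <- function(t, x, y, z, flash = NULL, fs = 100) {
  if (is.null(flash)) flash <- numeric(length(t))
  if (any(diff(t) <= 0))
    .stopf("timestamps must be strictly increasing before resampling",
           class = "validation_error")
  tu <- seq(t[1], t[length(t)], by = 1 / fs)
  li <- function(v) stats::approx(t, v, xout = tu)$y
  fl <- round(stats::approx(t, flash, xout = tu, method = "constant")$y)
  kinematic_series(tu, li(x), li(y), li(z), fl, fs = fs)
}

#' @export
print.cannula_trial <- function(x, ...) {
  cat(sprintf("<cannula_trial> %s / %s (fistula %d)\n",
              x$meta$participant_id, x$meta$trial_id, x$meta$fistula_id))
  print(x$series)
  invisible(x)
}
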