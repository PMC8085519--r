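#' Detect the skin-entry time of a trial
#'
#' The entry time is the timestamp of the first sample whose z position
#' lies strictly below the skin-surface height. Later re-emergences and
#' reinsertions do not move it: the constrained task runs from the first
#' puncture to the end of the record, which accommodates multiple
#' reinsertion attempts.
#'
#' @param series a [kinematic_series()].
#' @param skin_z skin-surface height (mm).
#' @return The entry timestamp (s).
#' @section Errors: if z never drops below `skin_z` the trial is
#'   unusable and a `no_entry_error` is raised (the analysis layer
#'   decides exclusion).
#' @export
detect_entry <- function(series, skin_z) {
  stopifnot(inherits(series, "kinematic_series"))
  idx <- which(series$z < skin_z)[1]
  if (is.na(idx))
    .stopf("needle never crossed the skin surface (z always >= %.3g mm)",
           skin_z, class = "no_entry_error")
  series$t[idx]
}

#' Extract flashback intervals from the LED channel
#'
#' Maximal runs of `flash == 1` are converted to closed time intervals
#' under a sample-and-hold convention: a run of k samples at spacing
#' `dt = 1/fs` covers `k * dt` seconds, ending one sample interval after
#' the run's last sample. This makes the flash ratio of an uninterrupted
#' channel exactly 1.
#'
#' @param series a [kinematic_series()].
#' @return list with `intervals` (two-column matrix `begin`,`end`; zero
#'   rows when the channel is all zeros) and `t_flash` (first onset, or
#'   `NA` when no sample is active).
#' @export
extract_flash_intervals <- function(series) {
  stopifnot(inherits(series, "kinematic_series"))
  dt <- 1 / series$fs
  r <- rle(series$flash)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values == 1
  if (!any(on)) {
    return(list(intervals = matrix(numeric(0), ncol = 2,
                                   dimnames = list(NULL, c("begin", "end"))),
                t_flash = NA_real_))
  }
  iv <- cbind(begin = series$t[starts[on]],
              end = series$t[ends[on]] + dt)
  list(intervals = iv, t_flash = unname(iv[1, 1]))
}

#' Segment a trial to the constrained task window
#'
#' Crops the kinematics to `[t_entry, t_end]`, where `t_entry` is the
#' first skin crossing ([detect_entry()]) and `t_end` is the expiry of
#' the final sample's hold (last timestamp + `1/fs`); flashback
#' intervals are extracted from the cropped record and clipped to the
#' window. All smoothness and outcome metrics are computed on this
#' segment -- without a consistent start and end point, smoothness
#' values are not comparable across trials.
#'
#' @param series a [kinematic_series()].
#' @param skin_z skin height (mm), or a [trial_meta()] whose `skin_z` is
#'   used.
#' @return An object of class `"task_segment"`: list with `t_entry`,
#'   `t_end`, `t_flash` (NA if no flashback), `flash_intervals`,
#'   `series` (cropped).
#' @export
segment_task <- function(series, skin_z) {
  if (inherits(skin_z, "trial_meta")) skin_z <- skin_z$skin_z
  t_entry <- detect_entry(series, skin_z)
  keep <- series$t >= t_entry
  dt <- 1 / series$fs
  cropped <- kinematic_series(series$t[keep], series$x[keep],
                              series$y[keep], series$z[keep],
                              series$flash[keep], fs = series$fs)
  t_end <- cropped$t[length(cropped$t)] + dt
  fi <- extract_flash_intervals(cropped)
  iv <- fi$intervals
  if (nrow(iv)) {
    iv[, "begin"] <- pmax(iv[, "begin"], t_entry)
    iv[, "end"] <- pmin(iv[, "end"], t_end)
    iv <- iv[iv[, "end"] > iv[, "begin"], , drop = FALSE]
  }
  t_flash <- if (nrow(iv)) unname(iv[1, "begin"]) else NA_real_
  structure(list(t_entry = t_entry, t_end = t_end, t_flash = t_flash,
                 flash_intervals = iv, series = cropped),
            class = "task_segment")
}

#' @export
print.task_segment <- function(x, ...) {
  cat(sprintf("<task_segment> [%.3f, %.3f] s (%d samples), %d flashback interval(s)\n",
              x$t_entry, x$t_end, length(x$series$t), nrow(x$flash_intervals)))
  invisible(x)
}
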