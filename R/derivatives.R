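# cache of Savitzky-Golay projection matrices; designing one is O(n^2)
# and dominates a cohort sweep if redone per trial
.sg_cache <- new.env(parent = emptyenv())

.sg_filter <- function(p, n, m, ts) {
  key <- sprintf("%d_%d_%d_%.17g", p, n, m, ts)
  f <- .sg_cache[[key]]
  if (is.null(f)) {
    f <- signal::sgolay(p = p, n = n, m = m, ts = ts)
    .sg_cache[[key]] <- f
  }
  f
}

#' Savitzky-Golay smoothed position and derivatives
#'
#' Estimates smoothed position, velocity, acceleration and jerk per axis
#' with a third-order Savitzky-Golay filter at the given window span --
#' local cubic least-squares fits yielding derivative orders 0-3 at
#' every sample. Edges are handled by fitting the terminal windows
#' (polynomial-fit extrapolation, no reflection padding), which matters
#' because segment boundaries dominate short cannulation trials.
#' Derivative scaling uses the true sample interval.
#'
#' The window span is the key smoothing parameter studied by this
#' package; the conventional sweep is `c(5, 25, 51, 101, 201)` samples
#' at 100 Hz (minimum, 1/4 s, 1/2 s, 1 s, 2 s).
#'
#' @param segment a `"task_segment"` (or a bare [kinematic_series()]).
#' @param window_span odd window length in samples, `> polyorder`, at
#'   most the segment length.
#' @param polyorder polynomial order of the local fits (default 3).
#' @return An object of class `"derivative_set"`: list with `t`,
#'   `window_span`, `fs`, and n-by-3 matrices `position` (mm),
#'   `velocity` (mm/s), `acceleration` (mm/s^2), `jerk` (mm/s^3), plus
#'   the scalar `speed` profile (mm/s, Euclidean norm of the velocity
#'   vector).
#' @section Errors: a segment shorter than the window raises a
#'   `short_segment_error`; the caller should drop the trial at that
#'   span.
#' @export
sg_derivatives <- function(segment, window_span, polyorder = 3) {
  series <- if (inherits(segment, "task_segment")) segment$series else segment
  stopifnot(inherits(series, "kinematic_series"))
  n <- length(series$t)
  if (window_span %% 2 != 1 || window_span < polyorder + 2)
    .stopf("window_span must be odd and > polyorder, got %s", window_span,
           class = "validation_error")
  if (window_span > n)
    .stopf("segment has %d samples, shorter than window span %d; drop this trial at this span",
           n, window_span, class = "short_segment_error")
  dt <- stats::median(diff(series$t))
  P <- matrix(0, n, 3); V <- P; A <- P; J <- P
  axes <- cbind(series$x, series$y, series$z)
  filt <- lapply(0:3, function(m)
    .sg_filter(polyorder, window_span, m, dt))
  for (ax in 1:3) {
    P[, ax] <- signal::sgolayfilt(axes[, ax], filt[[1]])
    V[, ax] <- signal::sgolayfilt(axes[, ax], filt[[2]])
    A[, ax] <- signal::sgolayfilt(axes[, ax], filt[[3]])
    J[, ax] <- signal::sgolayfilt(axes[, ax], filt[[4]])
  }
  structure(list(t = series$t, window_span = as.integer(window_span),
                 fs = series$fs, position = P, velocity = V,
                 acceleration = A, jerk = J,
                 speed = sqrt(rowSums(V^2))),
            class = "derivative_set")
}

#' Speed profile of a derivative set
#'
#' Per-sample Euclidean norm of the 3-D velocity estimate. Note this is
#' the tip speed, not the derivative of the (origin-dependent) distance
#' from the origin.
#'
#' @param dset a `"derivative_set"`.
#' @return numeric vector (mm/s), one value per sample.
#' @export
speed_profile <- function(dset) {
  stopifnot(inherits(dset, "derivative_set"))
  sqrt(rowSums(dset$velocity^2))
}

#' @export
print.derivative_set <- function(x, ...) {
  cat(sprintf("<derivative_set> span %d, %d samples, peak speed %.2f mm/s\n",
              x$window_span, length(x$t), max(x$speed)))
  invisible(x)
}
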