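#' Planar time series container
#'
#' A minimal container for uniformly sampled planar trajectories: marker
#' positions at 100 Hz or seat center-of-pressure samples at 56 Hz. Positions
#' are in meters; timestamps in seconds.
#'
#' @param time Numeric vector of timestamps (s), strictly increasing.
#' @param x,y Numeric coordinate vectors (m), same length as `time`.
#' @param rate Nominal sampling rate (Hz).
#' @return An object of class `ts_planar` with fields `time`, `x`, `y`, `rate`.
#' @export
ts_planar <- function(time, x, y, rate) {
  if (length(time) != length(x) || length(time) != length(y)) {
    stop("`time`, `x` and `y` must have equal lengths", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(time = as.numeric(time), x = as.numeric(x), y = as.numeric(y),
         rate = as.numeric(rate)),
    class = "ts_planar"
  )
}

#' @export
print.ts_planar <- function(x, ...) {
  cat(sprintf("<ts_planar> %d samples @ %g Hz, span %.3f s\n",
              length(x$time), x$rate,
              if (length(x$time) > 1) diff(range(x$time)) else 0))
  invisible(x)
}

#' @export
as.data.frame.ts_planar <- function(x, ...) {
  data.frame(t = x$time, x = x$x, y = x$y)
}

n_samples <- function(series) length(series$time)

duration_s <- function(series) {
  if (n_samples(series) < 2L) return(0)
  series$time[n_samples(series)] - series$time[1L]
}

#' Validate a planar time series
#'
#' Checks timestamp monotonicity and sample finiteness. Short runs of
#' non-finite coordinate samples (gaps up to `max_gap_s`) are repaired by
#' linear interpolation between the surrounding valid samples; longer gaps,
#' non-finite timestamps, and gaps at either end of the recording are
#' data-quality errors that name the offending interval.
#'
#' @param series A [ts_planar()] object.
#' @param max_gap_s Longest repairable gap in seconds (default 0.1 s, about
#'   ten samples at 100 Hz).
#' @return The validated (possibly repaired) `ts_planar` object.
#' @export
validate_series <- function(series, max_gap_s = 0.1) {
  stopifnot(inherits(series, "ts_planar"))
  t <- series$time
  if (length(t) < 2L) stop("series must contain at least 2 samples", call. = FALSE)
  if (any(!is.finite(t))) stop("non-finite timestamps", call. = FALSE)
  if (any(diff(t) <= 0)) {
    i <- which(diff(t) <= 0)[1L]
    stop(sprintf("timestamps not strictly increasing at sample %d (t = %.6f)",
                 i + 1L, t[i + 1L]), call. = FALSE)
  }
  for (axis in c("x", "y")) {
    v <- series[[axis]]
    bad <- !is.finite(v)
    if (!any(bad)) next
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      if (i0 == 1L || i1 == length(v)) {
        stop(sprintf("non-finite %s samples at the series boundary (samples %d-%d)",
                     axis, i0, i1), call. = FALSE)
      }
      gap <- t[i1 + 1L] - t[i0 - 1L]
      if (gap > max_gap_s) {
        stop(sprintf(
          "gap of %.3f s in %s (t = %.3f to %.3f) exceeds the %.3f s repair limit",
          gap, axis, t[i0 - 1L], t[i1 + 1L], max_gap_s), call. = FALSE)
      }
      v[i0:i1] <- stats::approx(
        x = t[c(i0 - 1L, i1 + 1L)], y = v[c(i0 - 1L, i1 + 1L)],
        xout = t[i0:i1])$y
    }
    series[[axis]] <- v
  }
  series
}
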