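#' Zero-phase Butterworth lowpass filter
#'
#' Applies an order-`order` Butterworth lowpass filter forward and backward
#' (zero phase) to each coordinate axis independently, the standard
#' preprocessing for motion-capture trajectories (10 Hz cutoff) and seat
#' center-of-pressure series (6 Hz cutoff). The dual pass squares the
#' single-pass magnitude response, so the effective attenuation at the
#' nominal cutoff is -6 dB (amplitude 0.5); phase lag is zero, which keeps
#' the timing of farthest-reach samples unbiased.
#'
#' @param series A validated [ts_planar()] object.
#' @param cutoff_hz Cutoff frequency (Hz); must be below the Nyquist rate.
#' @param order Filter order per pass (default 4).
#' @return A `ts_planar` object with filtered coordinates and unchanged
#'   timestamps.
#' @export
lowpass_filter <- function(series, cutoff_hz, order = 4L) {
  stopifnot(inherits(series, "ts_planar"))
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz <= 0) {
    stop("`cutoff_hz` must be a single positive number", call. = FALSE)
  }
  if (order < 1L || order %% 2L != 0L) {
    stop("`order` must be a positive even integer", call. = FALSE)
  }
  nyquist <- series$rate / 2
  if (cutoff_hz >= nyquist) {
    stop(sprintf("cutoff %.3g Hz is at or above the Nyquist frequency %.3g Hz",
                 cutoff_hz, nyquist), call. = FALSE)
  }
  if (n_samples(series) <= 3L * order) {
    stop(sprintf("series of %d samples is too short to filter stably (need > %d)",
                 n_samples(series), 3L * order), call. = FALSE)
  }
  bf <- signal::butter(order, W = cutoff_hz / nyquist, type = "low")
  series$x <- filtfilt_padded(bf, series$x)
  series$y <- filtfilt_padded(bf, series$y)
  series
}

# Forward-backward filtering with odd-reflection end padding: the dual pass
# is run on the padded signal so the zero-state startup transient decays
# inside the discarded pad instead of contaminating the series ends.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  p <- min(n - 1L, 512L)
  pre <- 2 * x[1L] - x[(p + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(p + 1L):(p + n)]
}
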