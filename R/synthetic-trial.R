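#' Generate one synthetic directional reach trial
#'
#' Emulates a single seated maximal reach of the postural star sitting test:
#' the fingertip follows a smooth minimum-jerk out-and-back displacement
#' profile along the direction's unit vector, with peak displacement equal to
#' `amplitude_m`, plus i.i.d. Gaussian positional noise emulating marker
#' jitter. The trunk center-of-mass trajectory is a scaled copy of the
#' noise-free fingertip displacement (coupling ratio `com_ratio`) with its
#' own proportionally scaled noise.
#'
#' @param direction One of the eight labels in [PSST_DIRECTIONS].
#' @param amplitude_m Peak fingertip displacement from start (m), > 0.
#' @param start Numeric length-2 start position (m); default the origin.
#' @param noise_sd_m SD of i.i.d. Gaussian positional noise (m).
#' @param duration_s Trial duration (s).
#' @param rate_hz Sampling rate (Hz), > 0.
#' @param com_ratio Ratio of center-of-mass to fingertip displacement.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A `reach_trial` object: list with `direction`, `fingertip` and
#'   `com` ([ts_planar()] objects) and `start_position`.
#' @export
generate_reach_trial <- function(direction, amplitude_m, start = c(0, 0),
                                 noise_sd_m = 0.005, duration_s = 2.5,
                                 rate_hz = 100, com_ratio = 0.35,
                                 seed = NULL) {
  direction <- match.arg(direction, PSST_DIRECTIONS)
  if (!is.numeric(amplitude_m) || length(amplitude_m) != 1L || amplitude_m <= 0) {
    stop("`amplitude_m` must be a single positive number", call. = FALSE)
  }
  if (rate_hz <= 0 || duration_s <= 0) {
    stop("`rate_hz` and `duration_s` must be positive", call. = FALSE)
  }
  if (noise_sd_m < 0) stop("`noise_sd_m` must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  t <- seq(0, duration_s, by = 1 / rate_hz)
  n <- length(t)
  s <- minimum_jerk_out_and_back(t / duration_s) * amplitude_m
  u <- direction_unit_vector(direction)

  fx <- start[1] + u[1] * s
  fy <- start[2] + u[2] * s
  cx <- start[1] + com_ratio * u[1] * s
  cy <- start[2] + com_ratio * u[2] * s
  if (noise_sd_m > 0) {
    fx <- fx + stats::rnorm(n, 0, noise_sd_m)
    fy <- fy + stats::rnorm(n, 0, noise_sd_m)
    cx <- cx + stats::rnorm(n, 0, noise_sd_m * com_ratio)
    cy <- cy + stats::rnorm(n, 0, noise_sd_m * com_ratio)
  }

  structure(
    list(direction = direction,
         fingertip = ts_planar(t, fx, fy, rate_hz),
         com = ts_planar(t, cx, cy, rate_hz),
         start_position = c(x = unname(start[1]), y = unname(start[2]))),
    class = "reach_trial"
  )
}

# Minimum-jerk out-and-back displacement profile on normalized time in [0, 1]:
# a 0 -> 1 minimum-jerk segment over the first half mirrored on the second,
# so displacement peaks at exactly 1 at mid-trial with zero velocity and
# acceleration at both ends.
minimum_jerk_out_and_back <- function(tau) {
  u <- ifelse(tau <= 0.5, tau / 0.5, (1 - tau) / 0.5)
  u <- pmin(pmax(u, 0), 1)
  10 * u^3 - 15 * u^4 + 6 * u^5
}

#' @export
print.reach_trial <- function(x, ...) {
  cat(sprintf("<reach_trial> direction %s, %d samples @ %g Hz\n",
              x$direction, length(x$fingertip$time), x$fingertip$rate))
  invisible(x)
}

#' Generate a synthetic center-of-pressure sway series
#'
#' Emulates seat center-of-pressure sway as a planar Ornstein-Uhlenbeck
#' process discretized at the pressure-mat rate (nominally 56 Hz), optionally
#' mixed with a deterministic circular oscillation. The diffusion scale sets
#' path length (hence total excursion and mean velocity); the mean-reversion
#' rate keeps sway bounded around the seat center; the regularity mix weight
#' `reg_mix` blends in the predictable oscillation, which lowers approximate
#' entropy without inflating path length.
#'
#' The mixed signal is `(1 - reg_mix) * OU + reg_mix * A * (sin, cos)` per
#' axis, where `A` is the stationary SD of the OU process, so the two
#' components have comparable magnitude at every mix weight.
#'
#' @param duration_s Series duration (s), > 0.
#' @param diffusion Diffusion scale of the OU process (m / sqrt(s)), >= 0.
#' @param theta Mean-reversion rate (1/s), >= 0.
#' @param reg_mix Deterministic-oscillation mixing weight in [0, 1].
#' @param osc_freq_hz Oscillation frequency (Hz).
#' @param rate_hz Sampling rate (Hz), default 56.
#' @param center Numeric length-2 sway center (m).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A [ts_planar()] object with subclass `cop_series`.
#' @export
generate_cop_series <- function(duration_s, diffusion = 0.022, theta = 1.0,
                                reg_mix = 0.35, osc_freq_hz = 0.4,
                                rate_hz = 56, center = c(0, 0), seed = NULL) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  if (diffusion < 0) stop("`diffusion` must be non-negative", call. = FALSE)
  if (theta < 0) stop("`theta` must be non-negative", call. = FALSE)
  if (reg_mix < 0 || reg_mix > 1) stop("`reg_mix` must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  dt <- 1 / rate_hz
  t <- seq(0, duration_s, by = dt)
  n <- length(t)

  ou_axis <- function() {
    z <- numeric(n)
    eps <- if (diffusion > 0) stats::rnorm(n - 1, 0, diffusion * sqrt(dt)) else numeric(n - 1)
    for (i in 2:n) z[i] <- z[i - 1] - theta * z[i - 1] * dt + eps[i - 1]
    z
  }
  ox <- ou_axis()
  oy <- ou_axis()

  # stationary SD of the OU component; falls back to a 1 cm scale when the
  # process is degenerate (zero diffusion or no mean reversion)
  amp <- if (theta > 0 && diffusion > 0) diffusion / sqrt(2 * theta) else 0.01
  if (reg_mix > 0) {
    ph <- 2 * pi * osc_freq_hz * t
    x <- (1 - reg_mix) * ox + reg_mix * amp * sin(ph)
    y <- (1 - reg_mix) * oy + reg_mix * amp * cos(ph)
    if (diffusion == 0 && reg_mix < 1) {
      # zero diffusion with no oscillation weight left on OU: OU term is 0
      x <- reg_mix * amp * sin(ph)
      y <- reg_mix * amp * cos(ph)
    }
  } else {
    x <- ox
    y <- oy
  }
  if (diffusion == 0 && reg_mix == 0) {
    x <- numeric(n)
    y <- numeric(n)
  }

  out <- ts_planar(t, center[1] + x, center[2] + y, rate_hz)
  class(out) <- c("cop_series", class(out))
  out
}

#' Generate synthetic 7-point Likert questionnaire responses
#'
#' Draws `n_items` integer item scores in 1..7 from a discretized truncated
#' normal centered at `1 + 6 * latent`, so the expected normalized sheet
#' score increases monotonically with the latent trait on [0, 1].
#'
#' @param latent Latent trait value in [0, 1].
#' @param n_items Number of items, >= 1.
#' @param item_sd SD of the item response distribution on the 1..7 scale;
#'   `0` makes every item the rounded center.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector of `n_items` scores in 1..7.
#' @export
generate_questionnaire <- function(latent, n_items, item_sd = 0.9, seed = NULL) {
  if (!is.numeric(latent) || length(latent) != 1L || latent < 0 || latent > 1) {
    stop("`latent` must be a single value in [0, 1]", call. = FALSE)
  }
  if (n_items < 1L) stop("`n_items` must be a positive integer", call. = FALSE)
  if (item_sd < 0) stop("`item_sd` must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  center <- 1 + 6 * latent
  raw <- if (item_sd > 0) stats::rnorm(n_items, center, item_sd) else rep(center, n_items)
  as.integer(pmin(7L, pmax(1L, round(raw))))
}
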