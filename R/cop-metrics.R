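#' Total excursion of a center-of-pressure series
#'
#' Sum of Euclidean step lengths between consecutive samples: how far the
#' center of pressure traveled over the epoch.
#'
#' @param cop A (filtered) [ts_planar()] / `cop_series` object with >= 2
#'   samples.
#' @return Total path length in meters.
#' @export
total_excursion <- function(cop) {
  stopifnot(inherits(cop, "ts_planar"))
  if (n_samples(cop) < 2L) stop("need at least 2 samples", call. = FALSE)
  sum(sqrt(diff(cop$x)^2 + diff(cop$y)^2))
}

#' Mean velocity of a center-of-pressure series
#'
#' Total excursion divided by the epoch duration, reported in cm/s (the
#' conventional posturography unit).
#'
#' @inheritParams total_excursion
#' @return Mean velocity in cm/s.
#' @export
mean_velocity <- function(cop) {
  dur <- duration_s(cop)
  if (dur <= 0) stop("series has zero duration", call. = FALSE)
  100 * total_excursion(cop) / dur
}

#' Approximate entropy of a scalar series
#'
#' Classic Pincus approximate entropy with self-matches included:
#' `ApEn = Phi_m(r) - Phi_{m+1}(r)` where
#' `Phi_m(r) = mean_i log C_i_m(r)` over the `N - m + 1` embedding vectors of
#' length `m`, and `C_i_m(r)` is the fraction of vectors within Chebyshev
#' distance `r` of vector `i`. Low values indicate regular, predictable
#' dynamics; higher values indicate complexity. Values conventionally fall
#' in 0-2, but some parameter choices (small absolute `r` on wide-band
#' signals) legitimately exceed 2: such values are flagged with a warning
#' and clipped only when `clip = TRUE`, never silently.
#'
#' @param signal Numeric vector, length > `m + 1`.
#' @param m Embedding length (samples), >= 1; default 2.
#' @param r Tolerance in signal units, > 0; default `0.2 * sd(signal)` (the
#'   Pincus convention).
#' @param clip If `TRUE`, clip the reported value to [0, 2]; default `FALSE`
#'   (flag out-of-range values but report them unchanged).
#' @return Approximate entropy (dimensionless).
#' @export
approximate_entropy <- function(signal, m = 2L, r = 0.2 * stats::sd(signal),
                                clip = FALSE) {
  signal <- as.numeric(signal)
  N <- length(signal)
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  if (N <= m + 1L) {
    stop(sprintf("series length %d is too short for m = %d (need > m + 1)",
                 N, m), call. = FALSE)
  }
  if (!is.finite(r) || r <= 0) {
    stop("`r` must be a positive tolerance (constant signals have sd 0; pass an absolute r)",
         call. = FALSE)
  }
  apen <- apen_phi(signal, m, r) - apen_phi(signal, m + 1L, r)
  if (apen > 2 || apen < 0) {
    warning(sprintf("ApEn %.4f lies outside the conventional 0-2 range%s",
                    apen, if (clip) "; clipping" else ""), call. = FALSE)
    if (clip) apen <- min(2, max(0, apen))
  }
  apen
}

# Phi_m(r): mean log correlation sum over embedding vectors of length m,
# computed with vectorized Chebyshev distances (one pmax layer per embedding
# dimension).
apen_phi <- function(signal, m, r) {
  N <- length(signal)
  n_vec <- N - m + 1L
  d <- abs(outer(signal[1:n_vec], signal[1:n_vec], "-"))
  if (m > 1L) {
    for (k in 1:(m - 1L)) {
      seg <- signal[(1L + k):(n_vec + k)]
      d <- pmax(d, abs(outer(seg, seg, "-")))
    }
  }
  C <- rowSums(d <= r) / n_vec
  mean(log(C))
}

#' Approximate entropy of a planar center-of-pressure series
#'
#' Reduces the planar series to a scalar signal and applies
#' [approximate_entropy()]. The default reduction is the centered resultant
#' displacement `sqrt(x_c^2 + y_c^2)` (a single scalar series capturing both
#' axes); `axis_mode = "per-axis-mean"` instead averages the per-axis
#' entropies, retained for sensitivity analysis.
#'
#' @param cop A (filtered) `cop_series` / [ts_planar()] object.
#' @param m Embedding length, default 2.
#' @param r_factor Tolerance as a fraction of the reduced signal's SD,
#'   default 0.2.
#' @param axis_mode `"resultant"` (default) or `"per-axis-mean"`.
#' @return Approximate entropy value. Degenerate constant series return 0.
#' @export
cop_apen <- function(cop, m = 2L, r_factor = 0.2,
                     axis_mode = c("resultant", "per-axis-mean")) {
  stopifnot(inherits(cop, "ts_planar"))
  axis_mode <- match.arg(axis_mode)
  one <- function(sig) {
    s <- stats::sd(sig)
    if (s == 0) return(0)  # constant signal: perfectly regular
    approximate_entropy(sig, m = m, r = r_factor * s)
  }
  if (axis_mode == "resultant") {
    sig <- sqrt((cop$x - mean(cop$x))^2 + (cop$y - mean(cop$y))^2)
    one(sig)
  } else {
    mean(c(one(cop$x), one(cop$y)))
  }
}
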