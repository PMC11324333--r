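#' Reaching directions of the postural star sitting test
#'
#' The eight principal reaching directions, at 45 degree increments in the
#' seated horizontal plane. The coordinate frame has its origin at the
#' neutral seated trunk position, `x` toward the dominant side and `y`
#' forward; `F` (front) is +y and `D` (dominant) is +x.
#'
#' @format Character vector of the eight direction labels: front (F),
#'   front-dominant (FD), dominant (D), back-dominant (BD), back (B),
#'   back-nondominant (BND), nondominant (ND), front-nondominant (FND).
#' @export
PSST_DIRECTIONS <- c("F", "FD", "D", "BD", "B", "BND", "ND", "FND")

.direction_angles_deg <- c(
  "F" = 90, "FD" = 45, "D" = 0, "BD" = -45,
  "B" = -90, "BND" = -135, "ND" = 180, "FND" = 135
)

#' Unit vector of a reaching direction
#'
#' @param direction One of the eight labels in [PSST_DIRECTIONS].
#' @return Numeric length-2 unit vector (x, y).
#' @export
direction_unit_vector <- function(direction) {
  direction <- match.arg(direction, PSST_DIRECTIONS)
  a <- .direction_angles_deg[[direction]] * pi / 180
  c(x = cos(a), y = sin(a))
}
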