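#' Farthest reach points over the eight directions
#'
#' Extracts, per direction, the sample of the chosen trajectory at maximum
#' distance from the trial start (the sitting stability limit in that
#' direction). Exactly one trial per direction is required.
#'
#' @param trials Named list of 8 `reach_trial` objects (one per direction).
#' @param use `"com"` (stability limits, default) or `"fingertip"`.
#' @return Data frame with columns `direction`, `x`, `y`.
#' @export
farthest_points <- function(trials, use = c("com", "fingertip")) {
  use <- match.arg(use)
  dirs <- vapply(trials, function(tr) tr$direction, character(1))
  if (anyDuplicated(dirs)) {
    stop("duplicate direction labels: ",
         paste(unique(dirs[duplicated(dirs)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(PSST_DIRECTIONS, dirs)
  if (length(missing)) {
    stop("missing direction(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  pts <- t(vapply(trials, farthest_point, numeric(2), use = use))
  data.frame(direction = dirs, x = pts[, "x"], y = pts[, "y"],
             row.names = NULL)
}

#' Star polygon over a set of boundary points
#'
#' Connects the points in counterclockwise angular order about their
#' centroid, forming the (possibly non-convex) sitting workspace polygon
#' over the eight farthest reach points.
#'
#' @param points Two-column matrix or data frame of planar points (m).
#' @return A `star_polygon`: list with `vertices` (n x 2 matrix, columns
#'   `x`, `y`, counterclockwise) and `centroid`.
#' @export
star_polygon <- function(points) {
  pts <- as_point_matrix(points)
  pts <- unique(pts)
  if (nrow(pts) < 3L) {
    stop("need at least 3 distinct points for a polygon", call. = FALSE)
  }
  centroid <- colMeans(pts)
  ang <- atan2(pts[, 2] - centroid[2], pts[, 1] - centroid[1])
  ord <- order(ang, sqrt((pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2))
  poly <- structure(list(vertices = pts[ord, , drop = FALSE], centroid = centroid),
                    class = "star_polygon")
  if (abs(shoelace_signed_area(poly$vertices)) < 1e-12) {
    stop("degenerate geometry: points are collinear", call. = FALSE)
  }
  poly
}

#' @export
print.star_polygon <- function(x, ...) {
  cat(sprintf("<star_polygon> %d vertices, area %.4g m^2\n",
              nrow(x$vertices), polygon_area(x)))
  invisible(x)
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  if (!is.matrix(points) || ncol(points) != 2L) {
    stop("`points` must be a two-column matrix or a data frame with x, y",
         call. = FALSE)
  }
  colnames(points) <- c("x", "y")
  points
}

shoelace_signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' Area of a workspace polygon
#'
#' Shoelace formula on the ordered vertices; the result is positive
#' regardless of orientation.
#'
#' @param poly A `star_polygon`.
#' @return Area in m^2.
#' @export
polygon_area <- function(poly) {
  stopifnot(inherits(poly, "star_polygon"))
  a <- abs(shoelace_signed_area(poly$vertices))
  if (a < 1e-12) stop("degenerate polygon has zero area", call. = FALSE)
  a
}

#' Convex hull of trajectory points
#'
#' The baseline reaching workspace is the minimal convex polygon
#' encompassing all baseline fingertip trajectory points. Vertices are
#' returned in counterclockwise order.
#'
#' @param points Two-column matrix or data frame of planar points (m).
#' @return A `star_polygon` whose vertices are the hull vertices.
#' @export
convex_hull <- function(points) {
  pts <- unique(as_point_matrix(points))
  if (nrow(pts) < 3L) {
    stop("need at least 3 distinct points for a hull", call. = FALSE)
  }
  idx <- grDevices::chull(pts[, 1], pts[, 2])  # clockwise order
  if (length(idx) < 3L) {
    stop("degenerate geometry: points are collinear", call. = FALSE)
  }
  v <- pts[rev(idx), , drop = FALSE]           # counterclockwise
  structure(list(vertices = v, centroid = colMeans(v)), class = "star_polygon")
}

#' Classify points against a polygon
#'
#' Vectorized ray-casting classification of planar points as `inside`,
#' `boundary` or `outside` a polygon. Points within `tol` of an edge are
#' `boundary` (and count as inside for activity-rate purposes).
#'
#' @param x,y Numeric vectors of query coordinates (m).
#' @param poly A `star_polygon`.
#' @param tol Boundary tolerance (m), default 1e-9.
#' @return Character vector in `c("inside", "boundary", "outside")`.
#' @export
point_in_polygon <- function(x, y, poly, tol = 1e-9) {
  stopifnot(inherits(poly, "star_polygon"))
  v <- poly$vertices
  n <- nrow(v)
  m <- length(x)
  if (length(y) != m) stop("`x` and `y` must have equal length", call. = FALSE)
  inside <- logical(m)
  on_edge <- logical(m)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    # distance from each query point to segment (x1,y1)-(x2,y2)
    ex <- x2 - x1; ey <- y2 - y1
    len2 <- ex^2 + ey^2
    tt <- if (len2 > 0) pmin(1, pmax(0, ((x - x1) * ex + (y - y1) * ey) / len2)) else 0
    dseg <- sqrt((x - (x1 + tt * ex))^2 + (y - (y1 + tt * ey))^2)
    on_edge <- on_edge | dseg <= tol
    # ray casting: horizontal ray toward +x
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  unname(ifelse(on_edge, "boundary", ifelse(inside, "inside", "outside")))
}

#' High-intense-activity rate of a training trajectory
#'
#' Fraction of training time the fingertip spends outside the baseline
#' reaching workspace polygon: `HIAR = high intense activity time / total
#' training time`. Each sample after the first contributes its preceding
#' inter-sample interval to the high-intense time when it is classified
#' outside the hull (boundary counts as inside); total time is the span of
#' the timestamps.
#'
#' @param fingertip A validated, filtered [ts_planar()] training trajectory.
#' @param baseline_hull A `star_polygon` (typically from [convex_hull()] of
#'   the baseline fingertip points).
#' @param tol Boundary tolerance passed to [point_in_polygon()].
#' @return List with `hiar` (dimensionless in [0, 1]), `high_intense_s` and
#'   `total_s`.
#' @export
hiar <- function(fingertip, baseline_hull, tol = 1e-9) {
  stopifnot(inherits(fingertip, "ts_planar"))
  if (n_samples(fingertip) < 2L) stop("empty or single-sample trajectory",
                                      call. = FALSE)
  cls <- point_in_polygon(fingertip$x, fingertip$y, baseline_hull, tol = tol)
  dt <- diff(fingertip$time)
  hi <- sum(dt[cls[-1L] == "outside"])
  total <- duration_s(fingertip)
  list(hiar = hi / total, high_intense_s = hi, total_s = total)
}
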