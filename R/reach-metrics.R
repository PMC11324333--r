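#' Functional reach test score of a trial
#'
#' The FRTS of a directional seated reach is the distance between the start
#' position and the farthest position attained by the chosen trajectory.
#' "Farthest" is the maximum Euclidean distance from the start over all
#' samples (ties broken by the earliest sample); an along-direction
#' projection variant is available via `mode = "projection"`.
#'
#' @param trial A `reach_trial` (validated and filtered upstream).
#' @param use Which trajectory to score: `"fingertip"` (the FRTS definition)
#'   or `"com"` (used for workspace stability limits).
#' @param mode `"euclidean"` (default) or `"projection"` (signed distance
#'   along the trial direction's unit vector).
#' @return List with `frts_m` (m) and `index` of the farthest sample.
#' @export
frts <- function(trial, use = c("fingertip", "com"),
                 mode = c("euclidean", "projection")) {
  stopifnot(inherits(trial, "reach_trial"))
  use <- match.arg(use)
  mode <- match.arg(mode)
  ts <- trial[[use]]
  if (n_samples(ts) < 1L) stop("empty trajectory", call. = FALSE)
  dx <- ts$x - trial$start_position[["x"]]
  dy <- ts$y - trial$start_position[["y"]]
  d <- if (mode == "euclidean") {
    sqrt(dx^2 + dy^2)
  } else {
    u <- direction_unit_vector(trial$direction)
    dx * u[["x"]] + dy * u[["y"]]
  }
  i <- which.max(d)  # which.max returns the earliest maximal sample
  list(frts_m = d[i], index = i)
}

#' Farthest-sample position of a trial
#'
#' Convenience wrapper around [frts()] returning the planar coordinates of
#' the farthest sample, used to build workspace polygons.
#'
#' @inheritParams frts
#' @return Named numeric vector `c(x =, y =)`.
#' @export
farthest_point <- function(trial, use = c("fingertip", "com"),
                           mode = c("euclidean", "projection")) {
  use <- match.arg(use)
  i <- frts(trial, use = use, mode = mode)$index
  ts <- trial[[use]]
  c(x = ts$x[i], y = ts$y[i])
}

#' Place the three-level reaching targets from baseline FRTS
#'
#' Basic targets sit at each direction's baseline farthest reach (distance =
#' FRTS along the ideal direction unit vector from the start); medium and
#' hard targets sit 10% and 20% of the FRTS farther away.
#'
#' @param frts_by_direction Named numeric vector of baseline FRTS per
#'   direction (m), all > 0, covering the 8 directions.
#' @param start Numeric length-2 start position (m).
#' @return Data frame with one row per direction x level: `direction`,
#'   `level` (`basic`/`medium`/`hard`), `distance_m`, `x`, `y`.
#' @export
place_targets <- function(frts_by_direction, start = c(0, 0)) {
  if (!setequal(names(frts_by_direction), PSST_DIRECTIONS)) {
    stop("`frts_by_direction` must name exactly the 8 directions", call. = FALSE)
  }
  if (any(frts_by_direction <= 0)) {
    stop("all FRTS values must be positive", call. = FALSE)
  }
  mult <- c(basic = 1.0, medium = 1.1, hard = 1.2)
  rows <- lapply(PSST_DIRECTIONS, function(d) {
    u <- direction_unit_vector(d)
    dist <- frts_by_direction[[d]] * mult
    data.frame(direction = d, level = names(mult), distance_m = unname(dist),
               x = start[1] + u[["x"]] * dist, y = start[2] + u[["y"]] * dist,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Cumulative reach task score of a training block
#'
#' Basic, medium and hard targets score 1, 2 and 3 points; a missed bout
#' scores 0. The task score is the cumulative score over the 96 training
#' bouts (12 rounds x 8 directions), so it ranges from 0 to 288.
#'
#' @param bout_levels Integer vector of exactly 96 reached-target levels in
#'   0..3 (0 = miss).
#' @return Integer cumulative score.
#' @export
reach_task_score <- function(bout_levels) {
  if (length(bout_levels) != 96L) {
    stop("expected exactly 96 bout levels, got ", length(bout_levels),
         call. = FALSE)
  }
  if (any(!bout_levels %in% 0:3)) {
    stop("bout levels must be integers in 0..3", call. = FALSE)
  }
  as.integer(sum(bout_levels))
}

#' Score training bouts against a target set
#'
#' Classifies each training bout by the highest target level whose
#' along-direction distance the bout's measured reach covers; undershooting
#' the basic target is a miss (level 0).
#'
#' @param bout_frts Numeric vector of per-bout measured reach distances (m).
#' @param bout_directions Character vector of per-bout direction labels.
#' @param targets Target set from [place_targets()].
#' @return Integer vector of levels in 0..3, one per bout.
#' @export
score_bouts <- function(bout_frts, bout_directions, targets) {
  if (length(bout_frts) != length(bout_directions)) {
    stop("`bout_frts` and `bout_directions` must have equal length", call. = FALSE)
  }
  vapply(seq_along(bout_frts), function(i) {
    td <- targets[targets$direction == bout_directions[i], ]
    if (nrow(td) != 3L) {
      stop("targets missing for direction ", bout_directions[i], call. = FALSE)
    }
    sum(bout_frts[i] >= sort(td$distance_m))
  }, integer(1))
}
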