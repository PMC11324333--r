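#' Normalize a 7-point Likert answer sheet
#'
#' Uniform normalization used for all five self-report instruments (SSQ,
#' ITQ, PQ, GEQ, UEQ): the sum of all item scores divided by the total
#' possible score `7 * n_items`. With items anchored 1..7 the attainable
#' range is [1/7, 1], not [0, 1]: an all-ones sheet scores 1/7.
#'
#' @param items Integer vector of item scores, each in 1..7, length >= 1.
#' @return Normalized score in (0, 1].
#' @export
normalize_likert <- function(items) {
  if (length(items) < 1L) stop("answer sheet has no items", call. = FALSE)
  if (any(!is.finite(items)) || any(items < 1 | items > 7) ||
      any(items != round(items))) {
    stop("item scores must be integers in 1..7", call. = FALSE)
  }
  sum(items) / (7 * length(items))
}

#' Normalize an objective immersion rating
#'
#' Positions a system on the reality-virtuality continuum: the rubric's raw
#' score divided by its maximum score, in [0, 1]. The physical-reality (PR)
#' arm is defined as 0 by convention.
#'
#' @param raw_score Raw rubric points, `0 <= raw_score <= max_score`.
#' @param max_score Maximum rubric points, > 0.
#' @param group Optional group label; `"PR"` returns 0 regardless of scores.
#' @return Normalized immersion score in [0, 1].
#' @export
normalize_immersion <- function(raw_score, max_score, group = NULL) {
  if (!is.null(group) && identical(group, "PR")) return(0)
  if (max_score <= 0) stop("`max_score` must be positive", call. = FALSE)
  if (raw_score < 0 || raw_score > max_score) {
    stop("`raw_score` must lie in [0, max_score]", call. = FALSE)
  }
  raw_score / max_score
}

#' Score every answer sheet of a subject
#'
#' Applies [normalize_likert()] per instrument x phase on a subject's
#' item-level responses.
#'
#' @param questionnaires Data frame with columns `instrument`, `phase`,
#'   `item`, `score`.
#' @return Data frame with columns `instrument`, `phase`, `score` (normalized).
#' @export
score_questionnaires <- function(questionnaires) {
  stopifnot(all(c("instrument", "phase", "score") %in% names(questionnaires)))
  key <- interaction(questionnaires$instrument, questionnaires$phase, drop = TRUE)
  out <- lapply(split(questionnaires, key), function(q) {
    data.frame(instrument = q$instrument[1L], phase = q$phase[1L],
               score = normalize_likert(q$score))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
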