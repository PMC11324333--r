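#' Serialize a cohort to a directory of CSV files
#'
#' Writes the plain-text interchange format of the pipeline:
#' `trajectories.csv` (subject, group, phase, round, bout, direction, t,
#' x_fingertip, y_fingertip, x_com, y_com), `cop.csv` (subject, group, phase,
#' round, t, x, y), `questionnaires.csv` (subject, group, instrument, phase,
#' item, score), `immersion.csv` (subject, group, raw_score, max_score) and
#' `manifest.yaml` echoing the generating configuration. Only the data
#' blocks present in the cohort are written.
#'
#' @param cohort A `psst_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "psst_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config

  traj <- list(); cop <- list(); quest <- list(); imm <- list()
  for (s in cohort$subjects) {
    if (!is.null(s$pre_trials)) {
      for (phase in c("pre", "post")) {
        trials <- if (phase == "pre") s$pre_trials else s$post_trials
        for (d in names(trials)) {
          tr <- trials[[d]]
          traj[[length(traj) + 1L]] <- data.frame(
            subject = s$subject_id, group = s$group, phase = phase,
            round = NA_integer_, bout = NA_integer_, direction = d,
            t = tr$fingertip$time,
            x_fingertip = tr$fingertip$x, y_fingertip = tr$fingertip$y,
            x_com = tr$com$x, y_com = tr$com$y)
        }
      }
    }
    if (!is.null(s$training_rounds)) {
      for (r in seq_along(s$training_rounds)) {
        rd <- s$training_rounds[[r]]
        traj[[length(traj) + 1L]] <- data.frame(
          subject = s$subject_id, group = s$group, phase = "training",
          round = r, bout = rd$bout, direction = rd$direction, t = rd$t,
          x_fingertip = rd$x_fingertip, y_fingertip = rd$y_fingertip,
          x_com = rd$x_com, y_com = rd$y_com)
      }
    }
    if (!is.null(s$cop_pre)) {
      cop_one <- function(series, phase, round = NA_integer_) {
        data.frame(subject = s$subject_id, group = s$group, phase = phase,
                   round = round, t = series$time, x = series$x, y = series$y)
      }
      cop[[length(cop) + 1L]] <- cop_one(s$cop_pre, "pre")
      cop[[length(cop) + 1L]] <- cop_one(s$cop_post, "post")
      for (r in seq_along(s$cop_by_round)) {
        cop[[length(cop) + 1L]] <- cop_one(s$cop_by_round[[r]], "training", r)
      }
    }
    if (!is.null(s$questionnaires)) {
      q <- s$questionnaires
      q$subject <- s$subject_id; q$group <- s$group
      quest[[length(quest) + 1L]] <- q[, c("subject", "group", "instrument",
                                           "phase", "item", "score")]
      imm[[length(imm) + 1L]] <- data.frame(
        subject = s$subject_id, group = s$group,
        raw_score = s$immersion[["raw"]], max_score = s$immersion[["max"]])
    }
  }

  write_one <- function(lst, file) {
    if (length(lst)) {
      utils::write.csv(do.call(rbind, lst), file.path(dir, file),
                       row.names = FALSE)
    }
  }
  write_one(traj, "trajectories.csv")
  write_one(cop, "cop.csv")
  write_one(quest, "questionnaires.csv")
  write_one(imm, "immersion.csv")

  manifest <- cfg
  class(manifest) <- NULL
  manifest$sway <- as.list(manifest$sway)
  manifest$likert <- as.list(manifest$likert)
  # yaml drops names on atomic vectors; store named vectors as maps
  manifest$baseline_reach_m <- as.list(manifest$baseline_reach_m)
  manifest$gain_by_group <- as.list(manifest$gain_by_group)
  manifest$round_curve$plateau <- as.list(manifest$round_curve$plateau)
  manifest$immersion$raw_score <- as.list(manifest$immersion$raw_score)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a serialized cohort back from a directory
#'
#' Inverse of [write_cohort()]: rebuilds a `psst_cohort` (subject records
#' with `ts_planar` trajectories) from the CSV/YAML interchange files.
#' Re-running the analysis on a round-tripped cohort reproduces the report
#' of the in-memory cohort.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `psst_cohort` object.
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(man_path)) stop("no manifest.yaml in ", dir, call. = FALSE)
  man <- yaml::read_yaml(man_path)
  cfg <- man
  cfg$sway <- as.data.frame(man$sway)
  cfg$likert <- as.data.frame(man$likert)
  cfg$baseline_reach_m <- unlist(man$baseline_reach_m)
  cfg$gain_by_group <- unlist(man$gain_by_group)
  cfg$round_curve$plateau <- unlist(man$round_curve$plateau)
  cfg$immersion$raw_score <- unlist(man$immersion$raw_score)
  class(cfg) <- "cohort_config"
  cfg <- validate_cohort_config(cfg)

  read_opt <- function(file) {
    p <- file.path(dir, file)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  traj <- read_opt("trajectories.csv")
  cop <- read_opt("cop.csv")
  quest <- read_opt("questionnaires.csv")
  imm <- read_opt("immersion.csv")

  ids <- unique(c(traj$subject, cop$subject, quest$subject))
  subjects <- lapply(ids, function(id) {
    rec <- list(subject_id = id)
    rec$group <- unique(c(traj$group[traj$subject == id],
                          cop$group[cop$subject == id],
                          quest$group[quest$subject == id]))[1L]
    if (!is.null(traj)) {
      st <- traj[traj$subject == id, ]
      for (phase in c("pre", "post")) {
        ph <- st[st$phase == phase, ]
        if (!nrow(ph)) next
        trials <- lapply(split(ph, ph$direction), function(dd) {
          structure(list(
            direction = dd$direction[1L],
            fingertip = ts_planar(dd$t, dd$x_fingertip, dd$y_fingertip,
                                  cfg$mocap_rate_hz),
            com = ts_planar(dd$t, dd$x_com, dd$y_com, cfg$mocap_rate_hz),
            start_position = c(x = dd$x_fingertip[1L], y = dd$y_fingertip[1L])),
            class = "reach_trial")
        })
        rec[[paste0(phase, "_trials")]] <- trials[PSST_DIRECTIONS]
      }
      trn <- st[st$phase == "training", ]
      if (nrow(trn)) {
        rec$training_rounds <- lapply(sort(unique(trn$round)), function(r) {
          rd <- trn[trn$round == r,
                    c("bout", "direction", "t", "x_fingertip", "y_fingertip",
                      "x_com", "y_com")]
          rownames(rd) <- NULL
          rd
        })
      }
    }
    if (!is.null(cop)) {
      sc <- cop[cop$subject == id, ]
      mk <- function(dd) {
        out <- ts_planar(dd$t, dd$x, dd$y, cfg$cop_rate_hz)
        class(out) <- c("cop_series", class(out))
        out
      }
      if (any(sc$phase == "pre")) rec$cop_pre <- mk(sc[sc$phase == "pre", ])
      if (any(sc$phase == "post")) rec$cop_post <- mk(sc[sc$phase == "post", ])
      trn <- sc[sc$phase == "training", ]
      if (nrow(trn)) {
        rec$cop_by_round <- lapply(sort(unique(trn$round)), function(r) {
          mk(trn[trn$round == r, ])
        })
      }
    }
    if (!is.null(quest)) {
      sq <- quest[quest$subject == id, c("instrument", "phase", "item", "score")]
      rownames(sq) <- NULL
      rec$questionnaires <- sq
    }
    if (!is.null(imm)) {
      si <- imm[imm$subject == id, ]
      if (nrow(si)) rec$immersion <- c(raw = si$raw_score[1L], max = si$max_score[1L])
    }
    class(rec) <- "subject_record"
    rec
  })

  structure(list(config = cfg, subjects = subjects), class = "psst_cohort")
}

#' Validate a subject record's design invariants
#'
#' Checks that reach phases cover exactly the eight directions, that the
#' training block has 12 rounds of 8 bouts each with levels in 0..3, and
#' that questionnaire scores lie on the 7-point scale.
#'
#' @param subject A subject record from a `psst_cohort`.
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_subject_record <- function(subject) {
  stopifnot(inherits(subject, "subject_record"))
  for (phase in c("pre_trials", "post_trials")) {
    trials <- subject[[phase]]
    if (is.null(trials)) next
    if (!setequal(names(trials), PSST_DIRECTIONS)) {
      stop(subject$subject_id, ": ", phase,
           " does not cover exactly the 8 directions", call. = FALSE)
    }
  }
  if (!is.null(subject$training_info)) {
    info <- subject$training_info
    if (!identical(sort(unique(info$round)), 1:12)) {
      stop(subject$subject_id, ": training must have rounds 1..12", call. = FALSE)
    }
    per_round <- table(info$round)
    if (any(per_round != 8L)) {
      stop(subject$subject_id, ": every round must have 8 bouts", call. = FALSE)
    }
    by_round_dirs <- tapply(info$direction, info$round,
                            function(d) setequal(d, PSST_DIRECTIONS))
    if (!all(unlist(by_round_dirs))) {
      stop(subject$subject_id, ": each round must cover all 8 directions",
           call. = FALSE)
    }
    if (any(!info$level %in% 0:3)) {
      stop(subject$subject_id, ": bout levels must be in 0..3", call. = FALSE)
    }
  }
  if (!is.null(subject$questionnaires)) {
    sc <- subject$questionnaires$score
    if (any(sc < 1L | sc > 7L | sc != round(sc))) {
      stop(subject$subject_id, ": questionnaire scores must be integers in 1..7",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
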