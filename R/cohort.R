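#' Configuration of a synthetic training-study cohort
#'
#' Bundles every parameter of the synthetic cohort generator: the three-arm
#' design (physical reality PR, augmented reality AR, virtual reality VR;
#' `n_per_group` subjects each), baseline reach amplitudes, multiplicative
#' pre-to-post reach gains per group, the saturating per-round learning
#' curve of the 12-round x 8-bout training block, Ornstein-Uhlenbeck sway
#' parameters per group and phase, and latent questionnaire traits per
#' instrument, phase and group. A single integer seed fixes all randomness.
#'
#' Default values encode the study conditions the generator emulates: 21
#' subjects per group, equal baselines across groups, larger reach gains in
#' the AR and VR arms than in the PR arm, post-training sway that is longer
#' and more complex in the AR/VR arms but faster only in the PR arm, and a
#' simulator-sickness increase confined to the VR arm.
#'
#' @param n_per_group Subjects per group, >= 2.
#' @param seed Integer seed fixing all generator randomness.
#' @param baseline_reach_m Named vector `c(mean =, sd =)`: subject-level
#'   baseline functional reach amplitude (m).
#' @param direction_sd_m SD of per-direction amplitude spread around the
#'   subject baseline (m).
#' @param gain_by_group Named multiplicative pre-to-post reach gains.
#' @param gain_sd Subject-level SD of the reach gain.
#' @param round_curve List with `tau_rounds` (learning-rate constant of the
#'   saturating exponential, in rounds), `plateau` (named per-group asymptotic
#'   fractional amplitude increase over baseline) and `bout_sd_m` (bout-level
#'   amplitude noise, m).
#' @param noise_sd_m Marker positional noise SD (m).
#' @param com_ratio Center-of-mass / fingertip displacement coupling ratio.
#' @param trial_duration_s Duration of an assessment reach trial (s).
#' @param training_bout_duration_s Duration of one training bout (s).
#' @param mocap_rate_hz Motion-capture sampling rate (Hz).
#' @param cop_rate_hz Pressure-mat sampling rate (Hz).
#' @param cop_round_duration_s Duration of each per-round sway epoch (s).
#' @param sway Data frame of sway parameters with columns `group`, `phase`
#'   (`pre`/`post`), `diffusion`, `theta`, `reg_mix`, `osc_freq_hz`,
#'   `duration_s`; per-round training sway interpolates pre -> post along the
#'   learning curve.
#' @param likert Data frame of latent questionnaire traits with columns
#'   `instrument`, `phase`, `group`, `latent_mean`, `latent_sd`, `n_items`.
#' @param item_sd Item-response SD on the 1..7 Likert scale.
#' @param immersion List with `max_score` and named `raw_score` per group
#'   (PR fixed at 0 on the reality-virtuality continuum).
#' @param components Character subset of
#'   `c("reach", "training", "cop", "questionnaires")` selecting which data
#'   blocks to synthesize (trimming blocks speeds up simulation studies that
#'   do not consume them).
#' @return A validated `cohort_config` object (a named list).
#' @export
cohort_config <- function(n_per_group = 21L,
                          seed = 20240901L,
                          baseline_reach_m = c(mean = 0.25, sd = 0.03),
                          direction_sd_m = 0.02,
                          gain_by_group = c(PR = 1.10, AR = 1.30, VR = 1.30),
                          gain_sd = 0.05,
                          round_curve = list(
                            tau_rounds = 3,
                            plateau = c(PR = 0.06, AR = 0.18, VR = 0.18),
                            bout_sd_m = 0.015),
                          noise_sd_m = 0.005,
                          com_ratio = 0.35,
                          trial_duration_s = 2.5,
                          training_bout_duration_s = 1.5,
                          mocap_rate_hz = 100,
                          cop_rate_hz = 56,
                          cop_round_duration_s = 15,
                          sway = default_sway_params(),
                          likert = default_likert_latents(),
                          item_sd = 0.9,
                          immersion = list(max_score = 40,
                                           raw_score = c(PR = 0, AR = 9, VR = 33)),
                          components = c("reach", "training", "cop",
                                         "questionnaires")) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    groups = c("PR", "AR", "VR"),
    baseline_reach_m = baseline_reach_m, direction_sd_m = direction_sd_m,
    gain_by_group = gain_by_group, gain_sd = gain_sd,
    round_curve = round_curve, noise_sd_m = noise_sd_m,
    com_ratio = com_ratio, trial_duration_s = trial_duration_s,
    training_bout_duration_s = training_bout_duration_s,
    mocap_rate_hz = mocap_rate_hz, cop_rate_hz = cop_rate_hz,
    cop_round_duration_s = cop_round_duration_s,
    sway = sway, likert = likert, item_sd = item_sd,
    immersion = immersion,
    n_rounds = 12L, n_bouts = 8L,
    components = components
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @param config A `cohort_config` object to validate.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_per_group < 2L) stop("`n_per_group` must be >= 2", call. = FALSE)
  if (config$baseline_reach_m[["mean"]] <= 0) {
    stop("baseline reach mean must be positive", call. = FALSE)
  }
  sds <- c(config$baseline_reach_m[["sd"]], config$direction_sd_m,
           config$gain_sd, config$noise_sd_m, config$round_curve$bout_sd_m,
           config$item_sd)
  if (any(sds < 0)) stop("all SD parameters must be >= 0", call. = FALSE)
  if (!setequal(names(config$gain_by_group), config$groups)) {
    stop("`gain_by_group` must name exactly the groups PR, AR, VR", call. = FALSE)
  }
  if (any(config$gain_by_group <= 0)) stop("group gains must be > 0", call. = FALSE)
  if (!setequal(names(config$round_curve$plateau), config$groups)) {
    stop("`round_curve$plateau` must name exactly the groups", call. = FALSE)
  }
  need <- c("group", "phase", "diffusion", "theta", "reg_mix",
            "osc_freq_hz", "duration_s")
  if (!all(need %in% names(config$sway))) {
    stop("`sway` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(config$sway$diffusion < 0)) stop("sway diffusion must be >= 0", call. = FALSE)
  bad <- setdiff(config$components,
                 c("reach", "training", "cop", "questionnaires"))
  if (length(bad)) stop("unknown components: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  config
}

#' Default sway parameters per group and phase
#'
#' Pre-training sway is matched across arms. Post-training sway emulates the
#' study's qualitative pattern: only the PR arm speeds up (larger diffusion),
#' the AR/VR arms sway longer (longer epochs) and more irregularly (smaller
#' deterministic-oscillation mix, i.e. higher approximate entropy).
#'
#' @return Data frame with one row per group x phase.
#' @export
default_sway_params <- function() {
  # the effective stochastic drive scales as (1 - reg_mix) * diffusion, so
  # diffusion is set jointly with the mix: sway speeds up after training only
  # in the PR arm, while the AR/VR arms sway longer (epoch duration) and
  # less regularly (smaller mix, higher entropy)
  rbind(
    data.frame(group = c("PR", "AR", "VR"), phase = "pre",
               diffusion = 0.044, theta = 1.0, reg_mix = 0.55,
               osc_freq_hz = 0.4, duration_s = 21),
    data.frame(group = c("PR", "AR", "VR"), phase = "post",
               diffusion = c(0.047, 0.025, 0.025), theta = 1.0,
               reg_mix = c(0.45, 0.20, 0.18),
               osc_freq_hz = 0.4, duration_s = c(27, 53, 51))
  )
}

#' Default latent questionnaire traits per instrument, phase and group
#'
#' Latent traits on [0, 1] feed [generate_questionnaire()]. Simulator
#' sickness (SSQ, 16 items) rises after training only in the VR arm;
#' immersive tendency (ITQ) is matched across arms at baseline; presence
#' (PQ) is administered to the AR and VR arms only; engagement (GEQ) and
#' enjoyment (UEQ) are higher in the AR/VR arms.
#'
#' @return Data frame with columns `instrument`, `phase`, `group`,
#'   `latent_mean`, `latent_sd`, `n_items`.
#' @export
default_likert_latents <- function() {
  rbind(
    data.frame(instrument = "SSQ", phase = "pre", group = c("PR", "AR", "VR"),
               latent_mean = c(0.15, 0.16, 0.15), latent_sd = 0.02, n_items = 16L),
    data.frame(instrument = "SSQ", phase = "post", group = c("PR", "AR", "VR"),
               latent_mean = c(0.16, 0.16, 0.20), latent_sd = 0.02, n_items = 16L),
    data.frame(instrument = "ITQ", phase = "pre", group = c("PR", "AR", "VR"),
               latent_mean = c(0.50, 0.51, 0.49), latent_sd = 0.055, n_items = 18L),
    data.frame(instrument = "PQ", phase = "post", group = c("AR", "VR"),
               latent_mean = c(0.38, 0.67), latent_sd = c(0.03, 0.05), n_items = 19L),
    data.frame(instrument = "GEQ", phase = "post", group = c("PR", "AR", "VR"),
               latent_mean = c(0.45, 0.70, 0.72), latent_sd = 0.08, n_items = 19L),
    data.frame(instrument = "UEQ", phase = "post", group = c("PR", "AR", "VR"),
               latent_mean = c(0.50, 0.72, 0.74), latent_sd = 0.08, n_items = 14L)
  )
}

# Saturating-exponential learning curve: fractional amplitude increase over
# baseline reached by round r (r = 1..12), with plateau `a` and rate `tau`.
round_gain_fraction <- function(round, plateau, tau_rounds) {
  plateau * (1 - exp(-round / tau_rounds))
}

#' Generate a seeded synthetic cohort
#'
#' Assembles the full study design: `3 * n_per_group` subjects, each with 8
#' pre-training and 8 post-training directional reach trials, a training
#' block of 12 rounds x 8 bouts in shuffled direction order with
#' reached-target levels, seat center-of-pressure series per phase and per
#' round, and item-level questionnaire responses. Post-training reach
#' amplitudes are the pre amplitudes scaled by the subject's group gain;
#' per-round training amplitudes follow the configured saturating learning
#' curve. All randomness derives from `config$seed`.
#'
#' @param config A [cohort_config()] object.
#' @return A `psst_cohort` object: list with `config` and `subjects` (a list
#'   of subject records).
#' @export
generate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  set.seed(config$seed)
  subjects <- list()
  idx <- 0L
  for (g in config$groups) {
    for (k in seq_len(config$n_per_group)) {
      idx <- idx + 1L
      subjects[[idx]] <- generate_subject(
        subject_id = sprintf("S%02d", idx), group = g, config = config)
    }
  }
  structure(list(config = config, subjects = subjects), class = "psst_cohort")
}

#' @export
print.psst_cohort <- function(x, ...) {
  cat(sprintf("<psst_cohort> %d subjects (%d per group), seed %d, components: %s\n",
              length(x$subjects), x$config$n_per_group, x$config$seed,
              paste(x$config$components, collapse = ", ")))
  invisible(x)
}

generate_subject <- function(subject_id, group, config) {
  ndir <- length(PSST_DIRECTIONS)
  base_subject <- stats::rnorm(1, config$baseline_reach_m[["mean"]],
                               config$baseline_reach_m[["sd"]])
  base <- pmax(0.05, base_subject + stats::rnorm(ndir, 0, config$direction_sd_m))
  names(base) <- PSST_DIRECTIONS
  gain <- max(0.5, stats::rnorm(1, config$gain_by_group[[group]], config$gain_sd))

  rec <- list(subject_id = subject_id, group = group,
              base_amplitudes = base, gain = gain)

  if ("reach" %in% config$components) {
    rec$pre_trials <- make_phase_trials(base, config)
    rec$post_trials <- make_phase_trials(base * gain, config)
  }

  if ("training" %in% config$components) {
    tr <- make_training_block(base, group, config)
    rec$training_info <- tr$info
    rec$training_rounds <- tr$rounds
  }

  if ("cop" %in% config$components) {
    rec$cop_pre <- make_cop(group, "pre", config)
    rec$cop_post <- make_cop(group, "post", config)
    rec$cop_by_round <- lapply(seq_len(config$n_rounds), function(r) {
      make_cop(group, "round", config, round = r)
    })
  }

  if ("questionnaires" %in% config$components) {
    rec$questionnaires <- make_questionnaires(group, config)
    rec$immersion <- c(raw = unname(config$immersion$raw_score[[group]]),
                       max = config$immersion$max_score)
  }

  class(rec) <- "subject_record"
  rec
}

make_phase_trials <- function(amplitudes, config) {
  trials <- lapply(PSST_DIRECTIONS, function(d) {
    generate_reach_trial(
      direction = d, amplitude_m = amplitudes[[d]],
      noise_sd_m = config$noise_sd_m, duration_s = config$trial_duration_s,
      rate_hz = config$mocap_rate_hz, com_ratio = config$com_ratio)
  })
  names(trials) <- PSST_DIRECTIONS
  trials
}

make_training_block <- function(base, group, config) {
  plateau <- config$round_curve$plateau[[group]]
  tau <- config$round_curve$tau_rounds
  bout_dur <- config$training_bout_duration_s
  info <- list()
  rounds <- vector("list", config$n_rounds)
  for (r in seq_len(config$n_rounds)) {
    dirs <- sample(PSST_DIRECTIONS)    # shuffled direction order per round
    frac <- round_gain_fraction(r, plateau, tau)
    round_traj <- vector("list", config$n_bouts)
    for (b in seq_len(config$n_bouts)) {
      d <- dirs[b]
      amp <- max(0.05, base[[d]] * (1 + frac) +
                   stats::rnorm(1, 0, config$round_curve$bout_sd_m))
      lvl <- target_level_reached(amp, base[[d]])
      trial <- generate_reach_trial(
        direction = d, amplitude_m = amp,
        noise_sd_m = config$noise_sd_m, duration_s = bout_dur,
        rate_hz = config$mocap_rate_hz, com_ratio = config$com_ratio)
      info[[length(info) + 1L]] <- data.frame(
        round = r, bout = b, direction = d, amplitude_m = amp, level = lvl)
      round_traj[[b]] <- data.frame(
        bout = b, direction = d,
        # trials span [0, bout_dur] inclusive; shift by one extra sample so
        # the concatenated round series stays strictly increasing and uniform
        t = trial$fingertip$time + (b - 1L) * (bout_dur + 1 / config$mocap_rate_hz),
        x_fingertip = trial$fingertip$x, y_fingertip = trial$fingertip$y,
        x_com = trial$com$x, y_com = trial$com$y)
    }
    rounds[[r]] <- do.call(rbind, round_traj)
  }
  list(info = do.call(rbind, info), rounds = rounds)
}

# Highest target level whose along-direction distance is covered by the bout
# amplitude; targets at the baseline amplitude (basic), 110% (medium) and
# 120% (hard). Undershooting the basic target is a miss (level 0).
target_level_reached <- function(amplitude, basic_distance) {
  sum(amplitude >= basic_distance * c(1.0, 1.1, 1.2))
}

make_cop <- function(group, phase, config, round = NULL) {
  sw_pre <- config$sway[config$sway$group == group & config$sway$phase == "pre", ]
  sw_post <- config$sway[config$sway$group == group & config$sway$phase == "post", ]
  if (nrow(sw_pre) != 1L || nrow(sw_post) != 1L) {
    stop("sway parameters must contain one pre and one post row per group",
         call. = FALSE)
  }
  if (phase == "round") {
    # per-round sway interpolates pre -> post along the learning curve
    w <- round_gain_fraction(round, 1, config$round_curve$tau_rounds)
    p <- lapply(c("diffusion", "theta", "reg_mix", "osc_freq_hz"), function(f) {
      (1 - w) * sw_pre[[f]] + w * sw_post[[f]]
    })
    names(p) <- c("diffusion", "theta", "reg_mix", "osc_freq_hz")
    dur <- config$cop_round_duration_s
  } else {
    sw <- if (phase == "pre") sw_pre else sw_post
    p <- as.list(sw[c("diffusion", "theta", "reg_mix", "osc_freq_hz")])
    dur <- sw$duration_s
  }
  generate_cop_series(duration_s = dur, diffusion = p$diffusion,
                      theta = p$theta, reg_mix = p$reg_mix,
                      osc_freq_hz = p$osc_freq_hz,
                      rate_hz = config$cop_rate_hz)
}

make_questionnaires <- function(group, config) {
  rows <- config$likert[config$likert$group == group, ]
  out <- list()
  for (i in seq_len(nrow(rows))) {
    # the configured latent is the target normalized sheet score; map it
    # through the inverse of the 1..7 normalization (score = 1/7 + 6/7 * L)
    # so generated sheets center near the target despite the 1/7 floor
    target <- min(1, max(0, stats::rnorm(1, rows$latent_mean[i], rows$latent_sd[i])))
    latent <- min(1, max(0, (7 * target - 1) / 6))
    items <- generate_questionnaire(latent, rows$n_items[i],
                                    item_sd = config$item_sd)
    out[[i]] <- data.frame(
      instrument = rows$instrument[i], phase = rows$phase[i],
      item = seq_along(items), score = items)
  }
  do.call(rbind, out)
}

#' Simulate a subject-level metric table without trajectory rendering
#'
#' Draws the same subject-level quantities as [generate_cohort()] — baseline
#' functional reach amplitudes per direction and a subject reach gain — but
#' returns the direction-averaged reach score per subject and test time
#' directly, skipping trajectory synthesis. This is the generator's
#' distribution-level path for ANOVA simulation studies (type-I error and
#' power/recovery rates over many seeded cohorts), where rendering and
#' re-measuring thousands of trajectories would only add the measurement
#' noise that the trajectory tests already characterize.
#'
#' @param config A [cohort_config()] object.
#' @return Data frame with columns `subject`, `group`, `time` (`T0`/`T1`) and
#'   `value` (mean reach amplitude, m); one row per subject x time.
#' @export
simulate_metric_table <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  set.seed(config$seed)
  ndir <- length(PSST_DIRECTIONS)
  rows <- list()
  idx <- 0L
  for (g in config$groups) {
    for (k in seq_len(config$n_per_group)) {
      idx <- idx + 1L
      base_subject <- stats::rnorm(1, config$baseline_reach_m[["mean"]],
                                   config$baseline_reach_m[["sd"]])
      base <- pmax(0.05, base_subject + stats::rnorm(ndir, 0, config$direction_sd_m))
      gain <- max(0.5, stats::rnorm(1, config$gain_by_group[[g]], config$gain_sd))
      rows[[idx]] <- data.frame(
        subject = sprintf("S%02d", idx), group = g,
        time = c("T0", "T1"), value = c(mean(base), mean(base) * gain))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
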