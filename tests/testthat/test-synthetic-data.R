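test_that("reach trials have the constructed peak displacement and are seeded", {
  tr <- generate_reach_trial("F", amplitude_m = 0.30, noise_sd_m = 0, seed = 1)
  d <- sqrt((tr$fingertip$x - tr$start_position[["x"]])^2 +
              (tr$fingertip$y - tr$start_position[["y"]])^2)
  expect_equal(max(d), 0.30, tolerance = 1e-12)
  # center-of-mass displacement is the configured fraction of fingertip
  dc <- sqrt((tr$com$x - tr$start_position[["x"]])^2 +
               (tr$com$y - tr$start_position[["y"]])^2)
  expect_equal(max(dc), 0.35 * 0.30, tolerance = 1e-12)

  a <- generate_reach_trial("BD", 0.25, noise_sd_m = 0.01, seed = 42)
  b <- generate_reach_trial("BD", 0.25, noise_sd_m = 0.01, seed = 42)
  expect_identical(a, b)

  expect_error(generate_reach_trial("F", -0.1), "positive")
  expect_error(generate_reach_trial("F", 0.3, rate_hz = 0), "positive")
})

test_that("mean measured peak of noisy reaches matches a Monte-Carlo oracle", {
  amp <- 0.30; noise <- 0.005; dur <- 2.5; rate <- 100
  # independent oracle: recompute the max-of-noisy-path expectation from the
  # displacement profile formula directly
  set.seed(99)
  tgrid <- seq(0, dur, by = 1 / rate)
  u <- tgrid / dur
  prof <- ifelse(u <= 0.5, u / 0.5, (1 - u) / 0.5)
  prof <- 10 * prof^3 - 15 * prof^4 + 6 * prof^5
  oracle_draws <- replicate(2000, {
    max(sqrt((amp * prof + rnorm(length(prof), 0, noise))^2 +
               rnorm(length(prof), 0, noise)^2))
  })
  oracle_mean <- mean(oracle_draws)

  set.seed(7)
  meas <- replicate(1000, {
    tr <- generate_reach_trial("F", amp, noise_sd_m = noise,
                               duration_s = dur, rate_hz = rate)
    frts(tr)$frts_m
  })
  se <- sqrt(stats::sd(meas)^2 / 1000 + stats::sd(oracle_draws)^2 / 2000)
  expect_lt(abs(mean(meas) - oracle_mean), 3 * se)
})

test_that("sway series are seeded, degenerate when told to, and respond to diffusion", {
  still <- generate_cop_series(5, diffusion = 0, reg_mix = 0, seed = 1)
  expect_equal(total_excursion(still), 0)

  a <- generate_cop_series(5, seed = 3)
  b <- generate_cop_series(5, seed = 3)
  expect_identical(a, b)
  expect_error(generate_cop_series(5, diffusion = -1), "non-negative")

  lo <- vapply(1:200, function(s) {
    total_excursion(generate_cop_series(5, diffusion = 0.01, seed = s))
  }, numeric(1))
  hi <- vapply(1:200, function(s) {
    total_excursion(generate_cop_series(5, diffusion = 0.03, seed = 1000 + s))
  }, numeric(1))
  expect_lt(stats::wilcox.test(hi, lo, alternative = "greater")$p.value, 1e-6)
})

test_that("questionnaire scores are degenerate at the latent extremes and monotone", {
  expect_true(all(generate_questionnaire(1, 12, item_sd = 0, seed = 1) == 7L))
  expect_true(all(generate_questionnaire(0, 12, item_sd = 0, seed = 1) == 1L))
  expect_error(generate_questionnaire(1.2, 10), "\\[0, 1\\]")

  set.seed(5)
  means <- vapply(c(0.2, 0.5, 0.8), function(lat) {
    mean(replicate(500, normalize_likert(generate_questionnaire(lat, 16))))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cohorts have the designed structure and are byte-reproducible", {
  cfg <- tiny_cohort_config(seed = 21)
  co <- generate_cohort(cfg)
  expect_length(co$subjects, 6L)
  expect_identical(as.integer(table(vapply(co$subjects, `[[`, "", "group"))),
                   rep(2L, 3))
  for (s in co$subjects) expect_true(validate_subject_record(s))

  co2 <- generate_cohort(cfg)
  expect_identical(co, co2)

  # post amplitudes are pre amplitudes scaled by the subject gain
  s1 <- co$subjects[[1]]
  expect_equal(unname(frts(preprocess_trial(s1$post_trials$F))$frts_m /
                        frts(preprocess_trial(s1$pre_trials$F))$frts_m),
               s1$gain, tolerance = 0.15)
})

test_that("metric-level simulation recovers the programmed group gains", {
  cfg <- cohort_config(n_per_group = 21, seed = 1234,
                       components = character(0))
  mt <- simulate_metric_table(cfg)
  ratios <- sapply(split(mt, mt$group), function(d) {
    wide <- merge(d[d$time == "T0", c("subject", "value")],
                  d[d$time == "T1", c("subject", "value")], by = "subject")
    r <- wide$value.y / wide$value.x
    c(mean = mean(r), se = stats::sd(r) / sqrt(nrow(wide)))
  })
  programmed <- cfg$gain_by_group[colnames(ratios)]
  expect_true(all(abs(ratios["mean", ] - programmed) < 3 * ratios["se", ]))
})

test_that("a null generator produces matched pre and post distributions", {
  # equal unit gains: pre and post values per group come from one distribution
  cfg0 <- function(seed) {
    cohort_config(n_per_group = 21, seed = seed,
                  gain_by_group = c(PR = 1, AR = 1, VR = 1),
                  components = character(0))
  }
  rejections <- vapply(1:100, function(s) {
    mt <- simulate_metric_table(cfg0(s))
    any(vapply(split(mt, mt$group), function(d) {
      stats::t.test(d$value[d$time == "T0"],
                    d$value[d$time == "T1"])$p.value < 0.05
    }, logical(1)))
  }, logical(1))
  expect_gte(sum(!rejections), 85)
})
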