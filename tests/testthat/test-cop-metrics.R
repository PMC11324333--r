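duration_s_for_test <- function(s) max(s$time) - min(s$time)

test_that("total excursion and mean velocity follow their definitions", {
  t <- seq(0, 2, by = 0.1)
  const <- ts_planar(t, rep(0.3, length(t)), rep(-0.1, length(t)), 10)
  expect_equal(total_excursion(const), 0)
  expect_equal(mean_velocity(const), 0)

  seg <- ts_planar(t, seq(0, 0.1, length.out = length(t)), rep(0, length(t)), 10)
  expect_equal(total_excursion(seg), 0.1, tolerance = 1e-12)
  expect_equal(mean_velocity(seg), 5.0, tolerance = 1e-12)

  set.seed(8)
  walk <- ts_planar(seq_len(1000) / 56, cumsum(rnorm(1000, 0, 1e-3)),
                    cumsum(rnorm(1000, 0, 1e-3)), 56)
  oracle <- 0
  for (i in 2:1000) {
    oracle <- oracle + sqrt((walk$x[i] - walk$x[i - 1])^2 +
                              (walk$y[i] - walk$y[i - 1])^2)
  }
  expect_equal(total_excursion(walk), oracle, tolerance = 1e-12)

  # path length dominates displacement; velocity x duration is the excursion
  expect_gte(total_excursion(walk),
             sqrt((walk$x[1000] - walk$x[1])^2 + (walk$y[1000] - walk$y[1])^2))
  expect_equal(mean_velocity(walk) * duration_s_for_test(walk) / 100,
               total_excursion(walk), tolerance = 1e-9)

  expect_error(total_excursion(ts_planar(0, 1, 1, 56)), "2 samples")
})

test_that("approximate entropy matches a naive double-loop oracle", {
  expect_equal(approximate_entropy(rep(1.5, 100), m = 2, r = 0.1), 0)

  alt <- rep(c(0, 1), length.out = 300)
  a_alt <- approximate_entropy(alt, m = 2, r = 0.1)
  expect_lt(a_alt, 0.05)
  expect_equal(a_alt, naive_apen(alt, 2, 0.1), tolerance = 1e-10)

  set.seed(21)
  noise <- runif(300)
  r <- 0.2 * sd(noise)
  a_noise <- approximate_entropy(noise, m = 2, r = r)
  expect_equal(a_noise, naive_apen(noise, 2, r), tolerance = 1e-10)
  expect_gt(a_noise, a_alt)

  expect_error(approximate_entropy(1:3, m = 2), "too short")
  expect_error(approximate_entropy(rep(1, 50), m = 2), "positive tolerance")
})

test_that("approximate entropy has the Pincus invariances", {
  set.seed(33)
  x <- as.numeric(arima.sim(list(ar = 0.7), 200))
  r <- 0.2 * sd(x)
  base <- approximate_entropy(x, 2, r)
  # shift invariance
  expect_equal(approximate_entropy(x + 5, 2, r), base, tolerance = 1e-12)
  # scale invariance when r scales along
  expect_equal(approximate_entropy(3 * x, 2, 3 * r), base, tolerance = 1e-12)
  # non-increasing in r on the coarse-tolerance branch (the ApEn-vs-r curve
  # is unimodal: at small r match counts saturate and the estimate dips)
  rs <- c(0.4, 0.8, 1.6, 2.4) * sd(x)
  vals <- vapply(rs, function(rr) approximate_entropy(x, 2, rr), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("planar reduction modes match their scalar oracles", {
  const <- generate_cop_series(5, diffusion = 0, reg_mix = 0, seed = 1)
  expect_equal(cop_apen(const), 0)

  cop <- generate_cop_series(8, seed = 14)
  res <- sqrt((cop$x - mean(cop$x))^2 + (cop$y - mean(cop$y))^2)
  expect_equal(cop_apen(cop), naive_apen(res, 2, 0.2 * sd(res)),
               tolerance = 1e-10)
  per_axis <- mean(c(naive_apen(cop$x, 2, 0.2 * sd(cop$x)),
                     naive_apen(cop$y, 2, 0.2 * sd(cop$y))))
  expect_equal(cop_apen(cop, axis_mode = "per-axis-mean"), per_axis,
               tolerance = 1e-10)
})

test_that("a stronger deterministic-oscillation mix lowers sway entropy", {
  apen_at <- function(mix, seed) {
    cop <- generate_cop_series(8, reg_mix = mix, seed = seed)
    cop_apen(preprocess_cop(cop))
  }
  regular <- vapply(1:30, function(s) apen_at(0.8, s), numeric(1))
  irregular <- vapply(1:30, function(s) apen_at(0.05, 500 + s), numeric(1))
  expect_lt(mean(regular), mean(irregular))
  expect_lt(stats::wilcox.test(regular, irregular,
                               alternative = "less")$p.value, 1e-4)
})
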