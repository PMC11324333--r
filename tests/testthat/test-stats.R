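test_that("split-plot ANOVA matches the cell-mean oracle and handles nulls", {
  # uniform time shift with group-mirrored baselines: group and interaction
  # sums of squares are exactly zero
  base <- c(1, 2, 3)
  tab <- do.call(rbind, lapply(c("PR", "AR", "VR"), function(g) {
    do.call(rbind, lapply(seq_along(base), function(k) {
      data.frame(subject = paste0(g, k), group = g, time = c("T0", "T1"),
                 value = c(base[k], base[k] + 0.5))
    }))
  }))
  an <- mixed_anova(tab)
  expect_equal(an$ss_effect[an$effect == "group"], 0, tolerance = 1e-12)
  expect_equal(an$ss_effect[an$effect == "interaction"], 0, tolerance = 1e-12)
  expect_gt(an$F[an$effect == "time"], 1e6)  # deterministic shift, zero error

  # hand-sized toy table against the independent sums-of-squares oracle
  toy <- make_mixed_table(n_per_group = 2, group_means = c(PR = 0, AR = 1, VR = 2),
                          time_effect = 1, interaction = c(PR = 0, AR = 0.5, VR = 1),
                          seed = 11)
  got <- mixed_anova(toy)
  oracle <- splitplot_ss_oracle(toy)
  expect_equal(got$ss_effect[got$effect == "group"],
               unname(oracle$ss["group"]), tolerance = 1e-8)
  expect_equal(got$ss_effect[got$effect == "time"],
               unname(oracle$ss["time"]), tolerance = 1e-8)
  expect_equal(got$ss_effect[got$effect == "interaction"],
               unname(oracle$ss["interaction"]), tolerance = 1e-8)
  expect_equal(got$F, unname(oracle$F[c("group", "time", "interaction")]),
               tolerance = 1e-8)
  expect_equal(got$df_num, unname(oracle$df[c("group", "time", "interaction")]))
  expect_equal(got$df_den, unname(oracle$df[c("subj_err", "within_err",
                                              "within_err")]))

  bad <- toy[-1, ]
  expect_error(mixed_anova(bad), "unbalanced")
})

test_that("sums of squares are conserved and partial eta-squared is bounded", {
  for (s in 1:25) {
    tab <- make_mixed_table(n_per_group = sample(3:8, 1),
                            group_means = rnorm(3) |>
                              stats::setNames(c("PR", "AR", "VR")),
                            time_effect = rnorm(1),
                            interaction = rnorm(3) |>
                              stats::setNames(c("PR", "AR", "VR")),
                            seed = 1000 + s)
    an <- mixed_anova(tab)
    o <- splitplot_ss_oracle(tab)
    ss_total <- sum((tab$value - mean(tab$value))^2)
    expect_equal(sum(o$ss), ss_total, tolerance = 1e-8)
    expect_equal(an$ss_effect[an$effect == "group"] +
                   an$ss_error[an$effect == "group"] +
                   an$ss_effect[an$effect == "time"] +
                   an$ss_effect[an$effect == "interaction"] +
                   an$ss_error[an$effect == "time"],
                 ss_total, tolerance = 1e-8)
    expect_true(all(an$partial_eta_sq >= 0 & an$partial_eta_sq <= 1))
  }
})

test_that("one-way ANOVA matches a direct sums-of-squares oracle", {
  v <- c(1, 1, 1, 1, 1, 1)
  null_an <- one_way_anova(v, rep(c("PR", "AR", "VR"), each = 2))
  expect_identical(null_an$F, 0)
  expect_identical(null_an$p, 1)

  set.seed(5)
  values <- c(rnorm(6, 0), rnorm(6, 0), rnorm(6, 1))
  groups <- rep(c("PR", "AR", "VR"), each = 6)
  an <- one_way_anova(values, groups)
  grand <- mean(values)
  m_g <- tapply(values, groups, mean)
  ss_b <- sum(6 * (m_g - grand)^2)
  ss_w <- sum((values - m_g[groups])^2)
  expect_equal(an$ss_effect, ss_b, tolerance = 1e-10)
  expect_equal(an$ss_error, ss_w, tolerance = 1e-10)
  expect_equal(an$F, (ss_b / 2) / (ss_w / 15), tolerance = 1e-10)
  expect_equal(an$partial_eta_sq, ss_b / (ss_b + ss_w), tolerance = 1e-10)

  expect_error(one_way_anova(values[1:7], groups[1:7]), "at least 2 values")
})

test_that("Bonferroni adjustment caps, scales and preserves order", {
  expect_equal(bonferroni_posthoc(0.01, k = 3), 0.03)
  expect_equal(bonferroni_posthoc(0.5, k = 3), 1.0)
  p <- c(0.001, 0.04, 0.2, 0.01)
  expect_identical(order(bonferroni_posthoc(p, 4)), order(p))
  expect_identical(bonferroni_posthoc(p), stats::p.adjust(p, "bonferroni"))
  expect_error(bonferroni_posthoc(1.2), "\\[0, 1\\]")
})

test_that("Levene's test is calibrated under the null and powered under the alternative", {
  null_p <- vapply(1:500, function(s) {
    set.seed(s)
    vals <- c(rnorm(21, 0), rnorm(21, 3), rnorm(21, -1))  # shifted means only
    levene_test(vals, rep(c("PR", "AR", "VR"), each = 21))$p
  }, numeric(1))
  expect_gt(stats::ks.test(null_p, "punif")$p.value, 0.01)

  power <- mean(vapply(1:200, function(s) {
    set.seed(10000 + s)
    vals <- c(rnorm(50, 0, 10), rnorm(50), rnorm(50))
    levene_test(vals, rep(c("PR", "AR", "VR"), each = 50))$p < 0.05
  }, logical(1)))
  expect_gt(power, 0.9)

  expect_error(levene_test(rep(1, 9), rep(c("a", "b", "c"), each = 3)),
               "degenerate")
})

test_that("normality checks are calibrated, powered, and guard degenerate input", {
  null_rate <- mean(vapply(1:500, function(s) {
    set.seed(s)
    normality_check(rnorm(21))$p < 0.05
  }, logical(1)))
  expect_gte(null_rate, 0.03)
  expect_lte(null_rate, 0.07)

  power <- mean(vapply(1:200, function(s) {
    set.seed(20000 + s)
    normality_check(rexp(50))$p < 0.05
  }, logical(1)))
  expect_gt(power, 0.8)

  expect_error(normality_check(rep(2, 10)), "constant")
  expect_error(normality_check(rnorm(2)), "3 <= n")
  qq <- normality_check(rnorm(21))$qq
  expect_identical(nrow(qq), 21L)
})

test_that("pairwise and within-group tests report sensible comparisons", {
  set.seed(9)
  values <- c(rnorm(10, 0), rnorm(10, 0.1), rnorm(10, 3))
  groups <- rep(c("PR", "AR", "VR"), each = 10)
  ph <- pairwise_group_tests(values, groups)
  expect_identical(nrow(ph), 3L)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 3))
  expect_lt(ph$p_adj[ph$group1 == "PR" & ph$group2 == "VR"], 0.01)

  tab <- make_mixed_table(n_per_group = 10, time_effect = 2, seed = 3)
  wt <- within_group_tests(tab)
  expect_identical(nrow(wt), 3L)
  expect_true(all(wt$p < 0.01))
  expect_true(all(wt$mean_change > 1))
})
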