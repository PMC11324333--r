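#' Split-plot (mixed between-within) ANOVA
#'
#' Two-way ANOVA with one between-subjects factor (group: PR/AR/VR) and one
#' within-subjects factor (test time: T0 baseline, T1 post-training), the
#' design used to compare intervention arms across the two assessments. The
#' between-subjects stratum (subject means) tests the group effect against
#' subjects-within-groups error; the within-subjects stratum tests time and
#' the group x time interaction against the subject x time residual. Partial
#' eta-squared for each effect is `SS_effect / (SS_effect + SS_error)` with
#' that effect's own error term. With two within-subject levels sphericity
#' holds trivially, so no correction is applied.
#'
#' @param table Data frame with columns `subject`, `group`, `time`, `value`;
#'   balanced (every subject has exactly one value per time).
#' @return Data frame of class `anova_result` with one row per effect
#'   (`group`, `time`, `interaction`): `df_num`, `df_den`, `F`, `p`,
#'   `partial_eta_sq`, `ss_effect`, `ss_error`.
#' @export
mixed_anova <- function(table) {
  df <- check_mixed_table(table)
  fit <- stats::aov(value ~ group * time + Error(subject), data = df)
  s <- summary(fit)
  btw <- s[["Error: subject"]][[1L]]
  wth <- s[["Error: Within"]][[1L]]
  pick <- function(tab, row) {
    i <- match(row, trimws(rownames(tab)))
    if (is.na(i)) stop("missing ANOVA term: ", row, call. = FALSE)
    j <- match("Residuals", trimws(rownames(tab)))
    f <- tab[["F value"]][i]
    p <- tab[["Pr(>F)"]][i]
    if (tab[["Sum Sq"]][i] == 0) { f <- 0; p <- 1 }  # exact null effect
    data.frame(
      df_num = tab$Df[i], df_den = tab$Df[j],
      F = f, p = p,
      partial_eta_sq = tab[["Sum Sq"]][i] /
        (tab[["Sum Sq"]][i] + tab[["Sum Sq"]][j]),
      ss_effect = tab[["Sum Sq"]][i], ss_error = tab[["Sum Sq"]][j])
  }
  out <- rbind(pick(btw, "group"), pick(wth, "time"), pick(wth, "group:time"))
  out <- cbind(effect = c("group", "time", "interaction"), out)
  rownames(out) <- NULL
  class(out) <- c("anova_result", class(out))
  out
}

check_mixed_table <- function(table) {
  need <- c("subject", "group", "time", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(subject = factor(table$subject),
                   group = factor(table$group),
                   time = factor(table$time),
                   value = as.numeric(table$value))
  if (any(!is.finite(df$value))) stop("non-finite metric values", call. = FALSE)
  counts <- table(df$subject, df$time)
  bad <- rownames(counts)[apply(counts, 1L, function(r) any(r != 1L))]
  if (length(bad)) {
    stop("unbalanced design: subject(s) without exactly one value per time: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  gmap <- tapply(as.character(df$group), df$subject, function(g) length(unique(g)))
  if (any(gmap != 1L)) {
    stop("subject(s) assigned to multiple groups: ",
         paste(names(gmap)[gmap != 1L], collapse = ", "), call. = FALSE)
  }
  per_group <- table(tapply(as.character(df$group), df$subject, unique))
  if (any(per_group < 2L)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }
  df
}

#' One-way between-groups ANOVA
#'
#' Standard between-groups decomposition for the time-invariant measures
#' (high-intense-activity rate, reach task score, questionnaire scores).
#' For the one-way design partial eta-squared equals eta-squared
#' (`SS_between / SS_total`).
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels, same length as `values`; >= 2 groups with
#'   >= 2 values each.
#' @return One-row data frame of class `anova_result` with `effect = "group"`,
#'   `df_num`, `df_den`, `F`, `p`, `partial_eta_sq`, `ss_effect`, `ss_error`.
#' @export
one_way_anova <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have equal length", call. = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) {
    stop("every group needs at least 2 values; offending: ",
         paste(levels(g)[table(g) < 2L], collapse = ", "), call. = FALSE)
  }
  if (stats::var(values) == 0) {
    # identical values within and across groups: no effect by definition
    out <- data.frame(effect = "group", df_num = nlevels(g) - 1L,
                      df_den = length(values) - nlevels(g),
                      F = 0, p = 1, partial_eta_sq = 0,
                      ss_effect = 0, ss_error = 0)
    class(out) <- c("anova_result", class(out))
    return(out)
  }
  tab <- stats::anova(stats::lm(values ~ g))
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  if (tab[["Sum Sq"]][1L] == 0) { f <- 0; p <- 1 }  # exact null effect
  out <- data.frame(
    effect = "group", df_num = tab$Df[1L], df_den = tab$Df[2L],
    F = f, p = p,
    partial_eta_sq = tab[["Sum Sq"]][1L] / sum(tab[["Sum Sq"]]),
    ss_effect = tab[["Sum Sq"]][1L], ss_error = tab[["Sum Sq"]][2L])
  class(out) <- c("anova_result", class(out))
  out
}

#' Bonferroni adjustment of pairwise p-values
#'
#' `p_adj = min(1, p * k)` for `k` comparisons. By convention pairwise
#' comparisons are only interpreted when the omnibus test is significant
#' (gatekeeping); see [pairwise_group_tests()].
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @param k Number of comparisons, >= 1; defaults to `length(p)`.
#' @return Adjusted p-values, same length as `p`.
#' @export
bonferroni_posthoc <- function(p, k = length(p)) {
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, p * k)
}

#' Pairwise group comparisons with Bonferroni correction
#'
#' Pooled-variance two-sample t-tests for every pair of groups, with
#' Bonferroni adjustment over the number of pairs. Used as the post-hoc
#' follow-up to a significant omnibus ANOVA.
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels.
#' @return Data frame with columns `group1`, `group2`, `t`, `df`, `p_raw`,
#'   `p_adj`.
#' @export
pairwise_group_tests <- function(values, groups) {
  g <- factor(groups)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[g == pairs[1L, i]]
    b <- values[g == pairs[2L, i]]
    tt <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                   error = function(e) NULL)  # essentially-constant data
    data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
               p_raw = if (is.null(tt)) NA_real_ else tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_posthoc(out$p_raw, k = nrow(out))
  out
}

#' Within-group pre/post paired comparisons
#'
#' Paired t-test of T1 against T0 per group, the within-group p-values
#' reported alongside the split-plot ANOVA.
#'
#' @param table Balanced mixed-design table as in [mixed_anova()].
#' @return Data frame with columns `group`, `t`, `df`, `p`, `mean_change`.
#' @export
within_group_tests <- function(table) {
  df <- check_mixed_table(table)
  times <- sort(levels(df$time))
  rows <- lapply(levels(df$group), function(gr) {
    sub <- df[df$group == gr, ]
    sub <- sub[order(sub$subject, sub$time), ]
    a <- sub$value[sub$time == times[1L]]
    b <- sub$value[sub$time == times[2L]]
    tt <- tryCatch(stats::t.test(b, a, paired = TRUE),
                   error = function(e) NULL)  # essentially-constant changes
    data.frame(group = gr,
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               mean_change = mean(b - a))
  })
  do.call(rbind, rows)
}

#' Levene's test of homoscedasticity
#'
#' One-way ANOVA on absolute deviations from the group center (mean by
#' default — classic Levene; median gives the Brown-Forsythe variant).
#' Reported alongside every between-groups ANOVA.
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels; >= 2 groups with >= 2 values each.
#' @param center `"mean"` (default) or `"median"`.
#' @return List with `statistic` (F), `df` (numerator, denominator), `p`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(groups)
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  cfun <- if (center == "mean") mean else stats::median
  dev <- abs(values - stats::ave(values, g, FUN = cfun))
  if (stats::var(dev) == 0) {
    stop("degenerate groups: all within-group deviations are identical",
         call. = FALSE)
  }
  tab <- car::leveneTest(values ~ g, center = cfun)
  list(statistic = tab[["F value"]][1L],
       df = c(tab$Df[1L], tab$Df[2L]),
       p = tab[["Pr(>F)"]][1L])
}

#' Shapiro-Wilk normality check with Q-Q coordinates
#'
#' Shapiro-Wilk test plus the Q-Q plot coordinates used for visual
#' inspection in the study report.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha Flagging level, default 0.05.
#' @return List with `W`, `p`, `flag` (`TRUE` when normality is rejected at
#'   `alpha`) and `qq` (data frame of theoretical and sample quantiles).
#' @export
normality_check <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n, call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("constant sample: normality test undefined (zero variance)",
         call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  qq <- stats::qqnorm(values, plot.it = FALSE)
  list(W = unname(sw$statistic), p = sw$p.value, flag = sw$p.value < alpha,
       qq = data.frame(theoretical = qq$x, sample = qq$y))
}
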