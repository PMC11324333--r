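# Independent oracles used across the test suite. Each deliberately takes a
# different computational route than the package implementation it checks.

# Naive approximate entropy: literal loop over template index i, Chebyshev
# distances accumulated dimension by dimension (the package builds a full
# distance matrix instead).
naive_apen <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    nv <- N - mm + 1L
    logC <- numeric(nv)
    for (i in seq_len(nv)) {
      dmax <- numeric(nv)
      for (k in 0:(mm - 1L)) {
        dmax <- pmax(dmax, abs(x[i + k] - x[(1:nv) + k]))
      }
      logC[i] <- log(sum(dmax <= r) / nv)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1L)
}

# Winding-number point-in-polygon oracle: total subtended angle, vectorized
# over query points. Returns "inside"/"outside" ("boundary" points land on
# either side; callers avoid or handle them).
winding_classify <- function(x, y, vertices) {
  n <- nrow(vertices)
  total <- numeric(length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- vertices[i, 1] - x; ay <- vertices[i, 2] - y
    bx <- vertices[j, 1] - x; by <- vertices[j, 2] - y
    total <- total + atan2(ax * by - ay * bx, ax * bx + ay * by)
  }
  ifelse(abs(total) > pi, "inside", "outside")
}

# Monte-Carlo polygon area by rejection sampling in the bounding box, using
# the winding-number oracle for the inside test.
mc_polygon_area <- function(vertices, n_points = 1e6, seed = 1) {
  set.seed(seed)
  xr <- range(vertices[, 1]); yr <- range(vertices[, 2])
  px <- stats::runif(n_points, xr[1], xr[2])
  py <- stats::runif(n_points, yr[1], yr[2])
  frac <- mean(winding_classify(px, py, vertices) == "inside")
  frac * diff(xr) * diff(yr)
}

# Brute-force O(n^3) convex hull: a directed pair (i, j) is a hull edge iff
# every other point lies strictly to its left; hull vertices are the points
# incident to some hull edge. Assumes points in general position.
brute_hull_vertex_ids <- function(pts) {
  n <- nrow(pts)
  on_hull <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cross <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
        (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
      if (all(cross[-c(i, j)] > 0)) on_hull[c(i, j)] <- TRUE
    }
  }
  which(on_hull)
}

# Cell-mean sums-of-squares oracle for the balanced two-group-factor
# split-plot design (between factor: group; within factor: time, 2 levels).
splitplot_ss_oracle <- function(df) {
  df$group <- as.character(df$group)
  df$time <- as.character(df$time)
  a <- length(unique(df$group))
  tt <- length(unique(df$time))
  n <- length(unique(df$subject)) / a
  grand <- mean(df$value)
  m_g <- tapply(df$value, df$group, mean)
  m_t <- tapply(df$value, df$time, mean)
  m_gt <- tapply(df$value, list(df$group, df$time), mean)
  m_s <- tapply(df$value, df$subject, mean)
  subj_group <- tapply(df$group, df$subject, function(g) g[1])

  ss_group <- tt * n * sum((m_g - grand)^2)
  ss_subj_err <- tt * sum((m_s - m_g[subj_group[names(m_s)]])^2)
  ss_time <- a * n * sum((m_t - grand)^2)
  ss_int <- n * sum((m_gt - outer(m_g, rep(1, tt)) -
                       outer(rep(1, a), m_t) + grand)^2)
  resid <- df$value - m_gt[cbind(df$group, df$time)] -
    m_s[df$subject] + m_g[df$group]
  ss_werr <- sum(resid^2)

  df_group <- a - 1; df_serr <- a * (n - 1)
  df_time <- tt - 1; df_int <- (a - 1) * (tt - 1)
  df_werr <- a * (n - 1) * (tt - 1)
  list(
    ss = c(group = ss_group, subj_err = ss_subj_err, time = ss_time,
           interaction = ss_int, within_err = ss_werr),
    F = c(group = (ss_group / df_group) / (ss_subj_err / df_serr),
          time = (ss_time / df_time) / (ss_werr / df_werr),
          interaction = (ss_int / df_int) / (ss_werr / df_werr)),
    df = c(group = df_group, subj_err = df_serr, time = df_time,
           interaction = df_int, within_err = df_werr)
  )
}

# Random star-shaped polygon: vertices at sorted angles with positive radii
# about the origin (guaranteed star-shaped about the centroid used here).
random_star_polygon <- function(n_vertices = 8, seed = 1) {
  set.seed(seed)
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  rad <- stats::runif(n_vertices, 0.2, 1)
  cbind(x = rad * cos(ang), y = rad * sin(ang))
}

# Fixed steady-state amplitude of a sinusoid within a filtered series,
# estimated by least squares on a central window (edge transients excluded).
fitted_sine_amplitude <- function(t, y, freq_hz, skip_s = 2) {
  keep <- t > min(t) + skip_s & t < max(t) - skip_s
  X <- cbind(sin(2 * pi * freq_hz * t[keep]), cos(2 * pi * freq_hz * t[keep]))
  cf <- stats::lm.fit(X, y[keep])$coefficients
  sqrt(sum(cf^2))
}

# Small balanced mixed-design table with controllable effects.
make_mixed_table <- function(n_per_group = 7, group_means = c(PR = 0, AR = 0, VR = 0),
                             time_effect = 0, interaction = c(PR = 0, AR = 0, VR = 0),
                             subject_sd = 1, noise_sd = 1, seed = 1) {
  set.seed(seed)
  rows <- list()
  id <- 0
  for (g in names(group_means)) {
    for (k in seq_len(n_per_group)) {
      id <- id + 1
      base <- group_means[[g]] + stats::rnorm(1, 0, subject_sd)
      y0 <- base + stats::rnorm(1, 0, noise_sd)
      y1 <- base + time_effect + interaction[[g]] + stats::rnorm(1, 0, noise_sd)
      rows[[id]] <- data.frame(subject = sprintf("S%03d", id), group = g,
                               time = c("T0", "T1"), value = c(y0, y1))
    }
  }
  do.call(rbind, rows)
}

# Tiny cohort configuration used wherever a full trajectory-level cohort is
# needed but its size is irrelevant to the property under test.
tiny_cohort_config <- function(seed = 7, n_per_group = 2, ...) {
  sway <- default_sway_params()
  sway$duration_s <- 6
  cohort_config(n_per_group = n_per_group, seed = seed,
                trial_duration_s = 1.0, training_bout_duration_s = 1.0,
                cop_round_duration_s = 5, sway = sway, ...)
}
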