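test_that("farthest points recover the construction and an exhaustive scan", {
  trials <- lapply(PSST_DIRECTIONS, function(d) {
    generate_reach_trial(d, 0.2, noise_sd_m = 0, duration_s = 1)
  })
  names(trials) <- PSST_DIRECTIONS
  pts <- farthest_points(trials, use = "fingertip")
  expect_equal(sqrt(pts$x^2 + pts$y^2), rep(0.2, 8), tolerance = 1e-9)

  dup <- trials; dup$FD <- dup$F
  expect_error(farthest_points(dup), "duplicate")
  expect_error(farthest_points(trials[1:7]), "missing direction")

  noisy <- lapply(PSST_DIRECTIONS, function(d) {
    generate_reach_trial(d, 0.2, noise_sd_m = 0.01, duration_s = 1,
                         seed = match(d, PSST_DIRECTIONS))
  })
  names(noisy) <- PSST_DIRECTIONS
  pts <- farthest_points(noisy, use = "com")
  for (d in PSST_DIRECTIONS) {
    tr <- noisy[[d]]
    dist <- sqrt((tr$com$x - tr$start_position[["x"]])^2 +
                   (tr$com$y - tr$start_position[["y"]])^2)
    i <- which.max(dist)
    expect_identical(unname(unlist(pts[pts$direction == d, c("x", "y")])),
                     c(tr$com$x[i], tr$com$y[i]))
  }
})

test_that("star polygons order vertices counterclockwise about the centroid", {
  sq <- rbind(c(1, 1), c(0, 0), c(0, 1), c(1, 0))
  colnames(sq) <- c("x", "y")
  poly <- star_polygon(sq)
  # counterclockwise: positive signed area under the shoelace formula
  v <- poly$vertices; n <- nrow(v); j <- c(2:n, 1)
  expect_gt(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2, 0)
  expect_equal(polygon_area(poly), 1)

  expect_error(star_polygon(cbind(x = c(0, 1, 2), y = c(0, 1, 2))), "collinear")
  expect_error(star_polygon(cbind(x = c(0, 1), y = c(0, 1))), "3 distinct")

  # ordering matches an exhaustive angular sort on random star point sets
  for (s in 1:20) {
    pts <- random_star_polygon(8, seed = s)
    shuffled <- pts[sample(nrow(pts)), , drop = FALSE]
    poly <- star_polygon(shuffled)
    ctr <- colMeans(unique(shuffled))
    ang <- atan2(poly$vertices[, 2] - ctr[2], poly$vertices[, 1] - ctr[1])
    # angles strictly increase once rotated to start at the minimum
    k <- which.min(ang)
    rot <- c(ang[k:length(ang)], ang[seq_len(k - 1)] + 2 * pi)
    expect_true(all(diff(rot) > 0))
  }
})

test_that("polygon areas match closed forms", {
  sq <- star_polygon(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  expect_equal(polygon_area(sq), 1)
  oct <- star_polygon(cbind(x = cos(2 * pi * (0:7) / 8),
                            y = sin(2 * pi * (0:7) / 8)))
  expect_equal(polygon_area(oct), 2 * sqrt(2), tolerance = 1e-12)
})

test_that("convex hulls contain their inputs and match a brute-force hull", {
  set.seed(12)
  pts <- rbind(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
               cbind(x = runif(20, 0.1, 0.9), y = runif(20, 0.1, 0.9)))
  h <- convex_hull(pts)
  expect_equal(polygon_area(h), 1)
  expect_equal(nrow(h$vertices), 4L)

  circ <- cbind(x = cos(2 * pi * (0:11) / 12), y = sin(2 * pi * (0:11) / 12))
  hc <- convex_hull(circ)
  expect_equal(nrow(hc$vertices), 12L)

  for (s in 1:10) {
    set.seed(100 + s)
    pts <- cbind(x = rnorm(40), y = rnorm(40))
    h <- convex_hull(pts)
    oracle <- pts[brute_hull_vertex_ids(pts), , drop = FALSE]
    got <- h$vertices
    expect_equal(nrow(got), nrow(oracle))
    ord <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
    expect_equal(unname(ord(got)), unname(ord(oracle)))
    inside <- point_in_polygon(pts[, 1], pts[, 2], h)
    expect_true(all(inside %in% c("inside", "boundary")))
  }

  expect_error(convex_hull(cbind(x = c(0, 1, 2), y = c(0, 1, 2))), "collinear")
})

test_that("point classification matches the winding-number oracle", {
  sq <- star_polygon(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  expect_identical(point_in_polygon(0.5, 0.5, sq), "inside")
  expect_identical(point_in_polygon(1, 1, sq), "boundary")
  expect_identical(point_in_polygon(1.5, 0.2, sq), "outside")

  for (s in 1:10) {
    pts <- random_star_polygon(8, seed = 300 + s)
    poly <- star_polygon(pts)
    set.seed(400 + s)
    qx <- runif(500, -1.2, 1.2); qy <- runif(500, -1.2, 1.2)
    got <- point_in_polygon(qx, qy, poly)
    oracle <- winding_classify(qx, qy, poly$vertices)
    off_boundary <- got != "boundary"
    expect_identical(got[off_boundary], oracle[off_boundary])
  }
})

test_that("hiar obeys its boundary cases and per-sample accounting", {
  sq <- star_polygon(cbind(x = c(-1, 1, 1, -1), y = c(-1, -1, 1, 1)))
  t <- seq(0, 5, by = 0.01)
  inside <- ts_planar(t, 0.2 * sin(t), 0.2 * cos(t), 100)
  expect_equal(hiar(inside, sq)$hiar, 0)
  outside <- ts_planar(t, 3 + 0.2 * sin(t), 0.2 * cos(t), 100)
  expect_equal(hiar(outside, sq)$hiar, 1)

  # first half inside, second half outside: ratio 0.5 within one sample
  n <- length(t)
  x <- c(rep(0, floor(n / 2)), rep(5, n - floor(n / 2)))
  half <- hiar(ts_planar(t, x, rep(0, n), 100), sq)
  expect_lt(abs(half$hiar - 0.5), 2 / n)
  expect_equal(half$hiar, half$high_intense_s / half$total_s)
})

test_that("workspace geometry is rigid-motion invariant and hull-monotone", {
  pts <- random_star_polygon(8, seed = 77)
  poly <- star_polygon(pts)
  a <- 1.1; R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  moved <- t(R %*% t(pts)) + matrix(c(2, -1), nrow(pts), 2, byrow = TRUE)
  colnames(moved) <- c("x", "y")
  expect_equal(polygon_area(star_polygon(moved)), polygon_area(poly),
               tolerance = 1e-12)

  t <- seq(0, 4, by = 0.01)
  traj <- ts_planar(t, 0.8 * cos(3 * t), 0.8 * sin(3 * t), 100)
  hull <- star_polygon(cbind(x = c(-1, 1, 1, -1), y = c(-1, -1, 1, 1)))
  h_full <- hiar(traj, hull)$hiar
  shrink <- function(k) {
    v <- hull$vertices
    ctr <- hull$centroid
    star_polygon(cbind(x = ctr[1] + k * (v[, 1] - ctr[1]),
                       y = ctr[2] + k * (v[, 2] - ctr[2])))
  }
  for (k in c(0.9, 0.7, 0.5)) {
    expect_gte(hiar(traj, shrink(k))$hiar, h_full)
  }

  # the convex hull over the extreme points covers the star polygon
  star <- star_polygon(pts)
  hull8 <- convex_hull(pts)
  expect_gte(polygon_area(hull8) + 1e-12, polygon_area(star))
})
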