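test_that("receptor occupancy follows the binding isotherm", {
  expect_equal(receptor_occupancy(0, kd = 12), 0)
  expect_equal(receptor_occupancy(12, kd = 12), 0.5)
  expect_equal(receptor_occupancy(108, kd = 12), 0.9)  # 108/120
  # monotone and saturating
  y <- receptor_occupancy(10^seq(-2, 6, by = 0.5), kd = 12)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0 & y < 1))
  expect_error(receptor_occupancy(-1), "non-negative")
  expect_error(receptor_occupancy(5, kd = 0), "positive")
})

test_that("overlapped nodes are the lattice points within the overlap radius", {
  f <- attractant_field(c(21, 21), dx = 4, conc = 10)
  on_node <- cell_agent(position = c(40, 40))   # node (11, 11), radius 6
  pts <- overlapped_points(on_node, f)
  expect_equal(nrow(pts), 9)  # centre, 4 at 4 um, 4 at sqrt(32) ~ 5.66 um
  # brute-force oracle over the whole lattice
  xy <- expand.grid(row = 1:21, col = 1:21)
  d <- sqrt(((xy$col - 1) * 4 - 40)^2 + ((xy$row - 1) * 4 - 40)^2)
  expect_setequal(paste(pts[, "row"], pts[, "col"]),
                  paste(xy$row[d <= 6], xy$col[d <= 6]))
  # radius below half a grid spacing: only the nearest node
  tiny <- cell_agent(position = c(40, 40), overlap_radius = 1.9)
  expect_equal(nrow(overlapped_points(tiny, f)), 1)
  # translating by one grid spacing translates the index set
  moved <- cell_agent(position = c(44, 40))
  pts2 <- overlapped_points(moved, f)
  expect_setequal(paste(pts2[, "row"], pts2[, "col"] - 1),
                  paste(pts[, "row"], pts[, "col"]))
})

test_that("the local gradient is a least-squares plane fit", {
  f <- attractant_field(c(21, 21), dx = 4, conc = 10)
  cell <- cell_agent(position = c(40, 40))
  expect_equal(local_gradient(cell, f), c(0, 0))   # uniform
  # exact linear field: recovered exactly
  xs <- (0:20) * 4
  f$conc <- outer(rep(1, 21), 2 + 0.5 * xs)
  expect_equal(local_gradient(cell, f), c(0.5, 0), tolerance = 1e-10)
  f$conc <- outer(3 + 0.25 * xs, rep(1, 21))      # gradient along y
  expect_equal(local_gradient(cell, f), c(0, 0.25), tolerance = 1e-10)
  # quadratic profile: fitted gradient matches the analytic derivative at the
  # centroid (symmetric stencil cancels the curvature term)
  f$conc <- outer(rep(1, 21), 0.01 * (xs - 10)^2)
  g <- local_gradient(cell, f)
  expect_equal(g[1], 0.02 * (40 - 10), tolerance = 0.05)
  expect_equal(g[2], 0, tolerance = 1e-10)
})

test_that("occupancy gradient collapses at saturating concentrations", {
  xs <- (0:20) * 4
  ramp <- outer(rep(1, 21), 100 + 0.5 * xs)
  f <- attractant_field(c(21, 21), dx = 4, conc = ramp)
  cell <- cell_agent(position = c(40, 40), kd = 12)
  g_low <- occupancy_gradient(cell, f)
  f$conc <- f$conc * 1e4    # same relative gradient, saturating absolute level
  g_high <- occupancy_gradient(cell, f)
  expect_gt(g_low[1], 0)
  expect_lt(sqrt(sum(g_high^2)) / sqrt(sum(g_low^2)), 1e-3)
})

test_that("heading proposals are persistent, and biased along the gradient", {
  cell <- cell_agent(position = c(0, 0), heading = 0.8)
  # vanishing dispersion and no bias: heading unchanged
  p0 <- motility_params(wrapped_normal_sigma = 1e-12, bias_strength = 0)
  expect_equal(propose_heading(cell, p0, c(0, 0)), 0.8, tolerance = 1e-9)
  # zero gradient: circular mean of many draws = current heading
  p <- motility_params(wrapped_normal_sigma = 0.6, bias_strength = 2)
  set.seed(42)
  th <- propose_heading(cell, p, c(0, 0), n = 1e5)
  se <- p$wrapped_normal_sigma / sqrt(1e5)
  expect_lt(abs(ang_diff(circ_mean(th), 0.8)), 3 * se + 1e-3)
  # overwhelming bias along +x pulls the mean to zero
  # (residual tilt ~ E[sin theta_p]/bias, so make the bias enormous)
  pb <- motility_params(wrapped_normal_sigma = 0.6, bias_strength = 1e4)
  th <- propose_heading(cell, pb, c(1, 0), n = 1e5)
  expect_lt(abs(circ_mean(th)), 3 * stats::sd(th) / sqrt(1e5) + 2e-4)
  expect_lt(stats::sd(th), 1e-3)
})

test_that("chemotactic alignment rises monotonically with bias strength", {
  cell <- cell_agent(position = c(0, 0), heading = pi / 2)
  set.seed(7)
  ci <- vapply(c(0, 0.5, 2), function(b) {
    p <- motility_params(wrapped_normal_sigma = 0.6, bias_strength = b)
    mean(cos(propose_heading(cell, p, c(1, 0), n = 2e4)))
  }, numeric(1))
  expect_true(all(diff(ci) > 0.05))
})

test_that("sub-threshold occupancy gradients weaken the steering bias", {
  cell <- cell_agent(position = c(0, 0), heading = pi)
  p <- motility_params(wrapped_normal_sigma = 0.6, bias_strength = 2,
                       sensing_scale = 2e-4)
  set.seed(11)
  ci_strong <- mean(cos(propose_heading(cell, p, c(1e-3, 0), n = 2e4)))
  ci_weak <- mean(cos(propose_heading(cell, p, c(1e-5, 0), n = 2e4)))
  expect_gt(ci_strong, 0.8)            # saturated bias dominates persistence
  expect_lt(ci_weak, 0.2)              # 5% of saturating scale: barely steers
})

test_that("cells move at constant speed and reflect at walls", {
  cell <- cell_agent(position = c(100, 100), heading = 0, speed = 10)
  moved <- move_cell(cell, dt = 60, extent = c(1000, 1000))
  expect_equal(moved$position, c(110, 100))
  expect_equal(move_cell(cell, 0, c(1000, 1000))$position, cell$position)
  # diagonal step length
  cell$heading <- pi / 3
  m2 <- move_cell(cell, 30, c(1000, 1000))
  expect_equal(sqrt(sum((m2$position - cell$position)^2)), 10 / 60 * 30)
  # a step that would exit reflects back inside with bounded displacement
  edge <- cell_agent(position = c(998, 500), heading = 0, speed = 10)
  r <- move_cell(edge, 60, c(1000, 1000))
  expect_true(r$position[1] <= 1000 && r$position[1] >= 0)
  expect_lte(sqrt(sum((r$position - edge$position)^2)), 10 / 60 * 60 + 1e-12)
  expect_equal(abs(ang_diff(r$heading, pi)), 0)   # normal component inverted
})

test_that("the occupancy average is a true sliding one-minute window", {
  cell <- cell_agent(position = c(0, 0))
  for (i in 1:90) cell <- update_occupancy_average(cell, 0.7, dt = 1)
  expect_equal(occupancy_average(cell), 0.7)
  # step input 0 -> 1 reaches 0.5 exactly 30 s after the step
  cell <- cell_agent(position = c(0, 0))
  cell <- update_occupancy_average(cell, 0, dt = 1)   # primes the window at 0
  for (i in 1:30) cell <- update_occupancy_average(cell, 1, dt = 1)
  expect_equal(occupancy_average(cell), 0.5)
  for (i in 1:30) cell <- update_occupancy_average(cell, 1, dt = 1)
  expect_equal(occupancy_average(cell), 1)
  # one sample spanning the whole window replaces the average outright
  cell2 <- cell_agent(position = c(0, 0))
  cell2 <- update_occupancy_average(cell2, 0, dt = 60)
  cell2 <- update_occupancy_average(cell2, 1, dt = 60)
  expect_equal(occupancy_average(cell2), 1)
  # average always stays within the window contents
  set.seed(3)
  cell3 <- cell_agent(position = c(0, 0))
  ys <- stats::runif(200)
  for (y in ys) {
    cell3 <- update_occupancy_average(cell3, y, dt = 1)
    expect_gte(occupancy_average(cell3), min(cell3$occ_buffer))
    expect_lte(occupancy_average(cell3), max(cell3$occ_buffer))
  }
})
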