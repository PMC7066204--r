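test_that("imposed bridges pin a linear source-sink gradient", {
  spec <- build_bridge(length = 1000, concentration = 300, mode = "imposed")
  f <- sggsim:::scenario_field(spec)
  # steady prefill: interior slope c_high / length = 0.3 nM/um
  xs <- (seq_len(ncol(f$conc)) - 1) * f$dx
  mid <- xs > 100 & xs < 940
  slopes <- diff(f$conc[3, mid]) / f$dx
  expect_equal(unique(round(slopes, 10)), 0.3)
  # strips pinned at both ends
  expect_true(all(f$fixed_mask[, xs < 40]))
  expect_true(all(f$fixed_mask[, xs > 1040]))
  expect_equal(unique(f$conc[f$fixed_mask & col(f$conc) < 5]), 0)
  # the 6 mm variant: slope 10 / 6 nM/um
  long <- build_bridge(length = 6000, concentration = 10000, mode = "imposed")
  fl <- sggsim:::scenario_field(long)
  xsl <- (seq_len(ncol(fl$conc)) - 1) * fl$dx
  midl <- xsl > 100 & xsl < 5900
  expect_equal(mean(diff(fl$conc[3, midl]) / fl$dx), 10000 / 6000,
               tolerance = 1e-6)
})

test_that("self-generated bridges start uniform with no pinned nodes", {
  spec <- build_bridge(concentration = 300, mode = "self")
  f <- sggsim:::scenario_field(spec)
  expect_true(all(f$conc == 300))
  expect_equal(sum(f$fixed_mask), 0)
})

test_that("population scans vary only the count and the seed", {
  specs <- build_population_scan(10000, c(50, 100, 200, 400), seed_base = 11)
  expect_length(specs, 4)
  expect_equal(vapply(specs, function(s) s$cells$n, integer(1)),
               as.integer(c(50, 100, 200, 400)))
  expect_equal(vapply(specs, function(s) s$seed, integer(1)), 11:14)
  expect_equal(vapply(specs, function(s) s$derived$total_vmax, numeric(1)),
               c(50, 100, 200, 400) * specs[[1]]$cells$vmax)
  # everything else identical
  strip <- function(s) { s$cells$n <- NULL; s$seed <- NULL; s$derived <- NULL; s }
  expect_identical(strip(specs[[1]]), strip(specs[[4]]))
  expect_error(build_population_scan(10000, numeric(0)), "non-empty")
})

test_that("two-spot geometry seeds the discs where the paper places them", {
  spec <- build_two_spot(10000)
  ctr <- sggsim:::two_spot_centers(spec)
  expect_equal(ctr$attractant[1] - ctr$cells[1], 1000)
  f <- sggsim:::scenario_field(spec)
  expect_equal(sample_concentration(f, ctr$attractant), 10000)
  expect_equal(sample_concentration(f, ctr$cells), 0)
  set.seed(1)
  cells <- sggsim:::scenario_cells(spec)
  d <- sqrt((cells[, "x"] - ctr$cells[1])^2 + (cells[, "y"] - ctr$cells[2])^2)
  expect_true(all(d <= spec$geometry$spot_radius))
  expect_error(build_two_spot(100, spot_radius = 600, separation = 500),
               "separation")
})

test_that("scenario validation names the offending field", {
  expect_error(build_bridge(concentration = -5), "c0")
  expect_error(build_bridge(width = -1), "width")
  expect_error(build_two_spot(1000, n_cells = -2), "cells\\$n")
  expect_error(build_bridge(logic = list(degradation = "sometimes")),
               "degradation")
  expect_error(build_bridge(cells = list(vmax = 0)), "vmax")
  expect_error(build_bridge(nonsense = 1), "unknown scenario field")
  expect_error(build_bridge(cells = list(colour = "red")), "cells\\$colour")
})

test_that("score_response counts initially seeded cells past the threshold", {
  pos0 <- cbind(rep(0, 10), 1:10)
  pos1 <- cbind(c(500, 450, 401, 400, 200, 100, 0, -50, 350, 600), 1:10)
  traj <- make_traj(c(0, 3600), list(pos0, pos1))
  expect_equal(score_response(traj, distance = 400, t = 3600), 0.4)
  expect_equal(score_response(traj, distance = 0, t = 3600), 0.8)
  # all or none
  expect_equal(score_response(make_traj(c(0, 3600),
    list(pos0, cbind(rep(500, 10), 1:10))), 400, 3600), 1)
  expect_equal(score_response(make_traj(c(0, 3600),
    list(pos0, pos0)), 400, 3600), 0)
  # monotone non-increasing in the distance threshold
  s <- vapply(c(0, 100, 200, 300, 401, 500),
              function(d) score_response(traj, d, 3600), numeric(1))
  expect_true(all(diff(s) <= 0))
  expect_error(score_response(traj, 400, t = 7200), "beyond")
})

test_that("time_to_pass finds the first crossing and censors cleanly", {
  # ballistic cell at 10 um/min: reaches 1000 um at exactly 100 min
  times <- seq(0, 7200, by = 60)
  pos <- lapply(times, function(t) cbind(10 * t / 60, 0))
  traj <- make_traj(times, pos)
  res <- time_to_pass(traj, n = 1, x = 1000)
  expect_equal(res$time_s, 6000)
  expect_false(res$censored)
  res2 <- time_to_pass(traj, n = 5, x = 1000)   # more cells than exist
  expect_true(res2$censored)
  expect_true(is.na(res2$time_s))
})

test_that("leading_distance averages the k front-most cells", {
  pos0 <- cbind(rep(0, 10), 1:10)
  pos1 <- cbind(seq(100, 1000, by = 100), 1:10)
  traj <- make_traj(c(0, 60), list(pos0, pos1))
  expect_equal(leading_distance(traj, k = 2, t = 60), 950)
  expect_equal(leading_distance(traj, k = 1, t = 60), 1000)
  expect_equal(leading_distance(traj, k = 10, t = 60), 550)
  expect_error(leading_distance(traj, k = 11, t = 60), "fewer than")
})

test_that("radial_leading_distance measures outward travel from the centre", {
  pos0 <- cbind(c(100, 100, 90), c(100, 110, 100))
  pos1 <- cbind(c(400, 100, 90), c(100, 110, 100))   # one cell moved 300 um out
  traj <- make_traj(c(0, 60), list(pos0, pos1))
  expect_equal(radial_leading_distance(traj, k = 1, t = 60, center = c(100, 100)),
               300)
  expect_equal(radial_leading_distance(make_traj(c(0, 60), list(pos0, pos0)),
                                       k = 3, t = 60, center = c(100, 100)), 0)
})

test_that("the two-spot score applies the 2x front-half rule", {
  mk <- function(front, back) {
    cbind(c(runif(front, 1, 10), runif(back, -10, -1)), 0)
  }
  set.seed(2)
  expect_true(score_two_spot(mk(10, 5), center = c(0, 0))$positive)
  expect_false(score_two_spot(mk(9, 5), center = c(0, 0))$positive)
  expect_true(score_two_spot(mk(1, 0), center = c(0, 0))$positive)
  # invariant under rigid rotation of the whole scene
  pos <- mk(10, 5)
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rot <- pos %*% t(Rm)
  expect_equal(score_two_spot(rot, center = c(0, 0),
                              direction = c(cos(th), sin(th)))$positive, TRUE)
  expect_equal(score_two_spot(rot, center = c(0, 0),
                              direction = c(cos(th), sin(th)))$front, 10)
})

test_that("under random placement the two-spot score matches the binomial tail", {
  # n = 15 cells uniform in the drop: front ~ Bin(15, 1/2); positive needs
  # front >= 2 back, i.e. front >= 10
  p_exact <- sum(stats::dbinom(10:15, 15, 0.5))
  set.seed(8)
  hits <- replicate(4000, {
    r <- 500 * sqrt(runif(15)); th <- runif(15, 0, 2 * pi)
    score_two_spot(cbind(r * cos(th), r * sin(th)), center = c(0, 0))$positive
  })
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(mean(hits) - p_exact), 3.5 * se)
})

test_that("scoring functions are pure", {
  pos0 <- cbind(rep(0, 10), 1:10)
  pos1 <- cbind(seq(100, 1000, by = 100), 1:10)
  traj <- make_traj(c(0, 3600), list(pos0, pos1))
  expect_identical(score_response(traj, 400, 3600),
                   score_response(traj, 400, 3600))
  expect_identical(time_to_pass(traj, 2, 500), time_to_pass(traj, 2, 500))
})
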