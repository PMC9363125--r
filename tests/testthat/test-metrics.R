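# brute-force reference for edge/width: scan the piecewise-linear interpolant
# (flat-extended to the domain ends) on a fine sub-grid
scan_profile <- function(om, centers, x_max, refine = 10) {
  dx_fine <- (centers[2] - centers[1]) / refine
  xs <- seq(0, x_max, by = dx_fine)
  ys <- stats::approx(centers, om, xout = xs, rule = 2)$y
  list(xs = xs, ys = ys, step = dx_fine)
}
edge_bruteforce <- function(om, centers, x_max, th, refine = 10) {
  s <- scan_profile(om, centers, x_max, refine)
  if (!any(s$ys >= th)) return(0)
  if (all(s$ys >= th)) return(x_max)
  max(s$xs[s$ys >= th])
}
width_bruteforce <- function(om, centers, x_max, th, refine = 10) {
  s <- scan_profile(om, centers, x_max, refine)
  sum(s$ys >= th) * s$step
}

test_that("edge location interpolates the rightmost threshold crossing", {
  expect_equal(edge_position(c(10, 6, 2), 4, grid = c(0, 50, 100),
                             x_max = 100), 75)
  expect_identical(edge_position(c(0, 0, 0), 1, grid = c(0, 50, 100),
                                 x_max = 100), 0)
  expect_identical(edge_position(c(10, 10, 10), 1, grid = c(0, 50, 100),
                                 x_max = 100), 100)
  expect_error(edge_position(c(1, 2), -1, grid = c(0, 50)), "threshold")
  expect_error(edge_position(c(1, 2), 0, grid = c(0, 50)), "threshold")
})

test_that("edge agrees with a 10x-refined scan on random monotone profiles", {
  set.seed(402)
  g <- discretize_domain(100, 40)
  for (i in 1:100) {
    om <- sort(stats::rexp(40, 1), decreasing = TRUE) * stats::runif(1, 0.5, 20)
    th <- stats::runif(1, min(om) * 1.01, max(om) * 0.99)
    ref <- edge_bruteforce(om, g$cell_centers, g$x_max, th)
    expect_lt(abs(edge_position(om, th, g) - ref), g$cell_width / 10 + 1e-9)
  }
})

test_that("edge position is monotone non-increasing in the threshold", {
  set.seed(77)
  g <- discretize_domain(100, 50)
  om <- sort(stats::rexp(50, 1), decreasing = TRUE)
  ths <- exp(seq(log(min(om[om > 0]) + 1e-6), log(max(om)), length.out = 60))
  e <- vapply(ths, function(t) edge_position(om, t, g), numeric(1))
  expect_true(all(diff(e) <= 1e-12))
})

test_that("active-region width measures the whole super-threshold set", {
  g3 <- c(0, 50, 100)
  expect_equal(active_region_width(c(10, 6, 2), 4, grid = g3, x_max = 100), 75)
  expect_identical(active_region_width(c(1, 1, 1), 2, grid = g3, x_max = 100), 0)
  # non-monotone bump on 3 wide cells: compare against the brute-force measure
  centers <- (seq_len(3) - 0.5) * 100 / 3
  om <- c(1, 5, 1)
  ref <- width_bruteforce(om, centers, 100, 4, refine = 1000)
  expect_equal(active_region_width(om, 4, grid = centers, x_max = 100), ref,
               tolerance = 5e-3)
  # detached from the source, the width is smaller than the edge position
  expect_lt(active_region_width(om, 4, grid = centers, x_max = 100),
            edge_position(om, 4, grid = centers, x_max = 100))
})

test_that("edge shift vanishes for identical runs and is symmetric", {
  g <- discretize_domain(100, 25)
  times <- seq(0, 1e3, length.out = 5)
  set.seed(9)
  omA <- outer(seq(0.1, 1, length.out = 5), exp(-seq(0, 5, length.out = 25)))
  omB <- omA * 1.3
  trA <- synthetic_traj(omA, times, g)
  trB <- synthetic_traj(omB, times, g)
  same <- edge_shift(trA, trA)
  expect_true(all(same$shift == 0))
  ths <- c(0.05, 0.2, 0.5)
  ab <- edge_shift(trA, trB, ths)
  ba <- edge_shift(trB, trA, ths)
  expect_equal(ab$shift, ba$shift)
  gg <- discretize_domain(100, 26)
  trC <- synthetic_traj(matrix(1, 5, 26), times, gg)
  expect_error(edge_shift(trA, trC), "share grid")
})

test_that("kymograph rows reproduce the trajectory's activity profiles", {
  tr <- simulate_trajectory(wnt_scenario(), wnt_params(t_max = 2e3),
                            discretize_domain(100, 25), n_time_samples = 6)
  K <- kymograph(tr)
  expect_identical(dim(K), c(6L, 25L))
  expect_identical(unname(K), unname(tr$states[, , "omega"]))
  # a single-snapshot trajectory cannot form a kymograph
  one <- synthetic_traj(matrix(1, 1, 25), 0, discretize_domain(100, 25))
  expect_error(kymograph(one), "at least 2")
})

test_that("steady-edge time finds when the boundary stops moving", {
  g <- discretize_domain(100, 25)
  times <- seq(0, 1e4, length.out = 11)
  base <- exp(-g$cell_centers / 20)
  # edge frozen from the start
  om_const <- matrix(rep(10 * base, each = 11), 11, 25)
  expect_identical(as.numeric(time_to_steady_edge(
    synthetic_traj(om_const, times, g), 1)), 0)
  # edge moves until the penultimate sample
  grow <- seq(0.1, 10, length.out = 11)
  om_grow <- outer(grow, base) * 10
  t_grow <- time_to_steady_edge(synthetic_traj(om_grow, times, g), 1)
  expect_gt(as.numeric(t_grow), 0)
  expect_true(attr(t_grow, "threshold_crossed"))
  # threshold never crossed: returns t_max flagged
  t_none <- time_to_steady_edge(synthetic_traj(om_const, times, g), 1e6)
  expect_identical(as.numeric(t_none), 1e4)
  expect_false(attr(t_none, "threshold_crossed"))
  expect_error(time_to_steady_edge(synthetic_traj(om_const, times, g), 1,
                                   epsilon = -1), "epsilon")
})

test_that("edge traces cover every requested threshold and time", {
  tr <- simulate_trajectory(wnt_scenario(), wnt_params(t_max = 2e3),
                            discretize_domain(100, 25), n_time_samples = 6)
  et <- edge_trace(tr, thresholds = c(1e-4, 1e-3, 1e-2))
  expect_identical(dim(et$edge_positions), c(3L, 6L))
  expect_true(all(et$edge_positions >= 0 & et$edge_positions <= 100))
})
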