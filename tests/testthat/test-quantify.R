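test_that("summary statistics respect se = sd / sqrt(n)", {
  set.seed(1)
  v <- rnorm(40, 10, 2)
  s <- summary_stat(v)
  expect_equal(s$se, s$sd / sqrt(s$n))
  expect_equal(s$n, 40L)
  expect_error(summary_stat(numeric(0)), "at least one")
})

test_that("cytosol width matches a direct minor-axis percentile oracle", {
  set.seed(21)
  pts <- sample_cell_points(default_geom(), 1e5)
  w <- cytosol_width(pts)
  # oracle: the generator's true minor axis is y; same percentile gesture
  oracle <- diff(quantile(pts[, 2], c(0.01, 0.99), names = FALSE))
  expect_equal(w, oracle, tolerance = 0.005)
  # known percentile bias of a filled 2400 nm cell: a few percent low
  expect_gt(w / 2400, 0.96)
  expect_lt(w / 2400, 0.995)
  expect_error(cytosol_width(pts[1:50, ]), "100")
})

test_that("cytosol width is exactly scale-equivariant and rotation-invariant", {
  set.seed(22)
  pts <- sample_cell_points(default_geom(), 5000)
  expect_equal(cytosol_width(pts * 4.9) / cytosol_width(pts), 4.9,
               tolerance = 1e-12)
  # isotropic disk: the same span on any axis
  disk <- sample_cell_points(cell_geometry(length = 2400, width = 2400),
                             20000)
  th <- 0.7
  rot <- disk %*% rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(cytosol_width(rot), cytosol_width(disk), tolerance = 0.01)
})

test_that("nuclear diameter is exact for disks and oracle-calibrated for rings", {
  # filled disk of diameter 2360 nm: half-maximum crossing at the edge
  grid <- expand.grid(x = seq(-1150, 1150, by = 50),
                      y = seq(-1150, 1150, by = 50))
  grid <- grid[grid$x^2 + grid$y^2 <= 1180^2, ]
  disk <- simulate_spot_stack(as.matrix(grid) + 32 * 129, 100, 1.1, 0, 1,
                              dim = c(64, 64), noise = FALSE)
  expect_equal(nuclear_diameter(disk), 2360, tolerance = 129 / 2360)

  # thin ring blurred by the PSF: the outer half-maximum sits
  # sqrt(2 log 2) * sigma_psf beyond the ring radius
  ring <- ring_positions(center = c(32, 32) * 129, diameter = 2360, n = 180)
  stk <- simulate_spot_stack(ring, 1000, 1.1, 0, 1, dim = c(64, 64),
                             noise = FALSE)
  oracle <- 2360 + 2 * sqrt(2 * log(2)) * 1.1 * 129
  expect_equal(nuclear_diameter(stk), oracle, tolerance = 0.03)
  # the peak rule reads the ring radius itself
  expect_equal(nuclear_diameter(stk, rule = "peak"), 2360, tolerance = 0.08)

  dark <- image_stack(matrix(5, 32, 32), 129)
  expect_error(nuclear_diameter(dark), "no nuclear signal")
})

test_that("nuclear diameter scales with a global coordinate scaling", {
  k <- 4.9
  ring <- ring_positions(center = c(32, 32) * 129, diameter = 480, n = 180)
  small <- simulate_spot_stack(ring, 1000, 1.1, 0, 1, dim = c(64, 64),
                               noise = FALSE)
  big_ring <- ring_positions(center = c(160, 160) * 129, diameter = 480 * k,
                             n = 360)
  big <- simulate_spot_stack(big_ring, 1000, 1.1 * k, 0, 1, dim = c(320, 320),
                             noise = FALSE)
  expect_equal(nuclear_diameter(big) / nuclear_diameter(small), k,
               tolerance = 0.02)
})

test_that("expansion factors reproduce the worked ratios with propagated errors", {
  expect_equal(round(expansion_factor(11.8, 2.4)$factor, 1), 4.9)
  expect_equal(round(expansion_factor(11.6, 2.36)$factor, 1), 4.9)
  same <- expansion_factor(as_summary_stat(5), as_summary_stat(5))
  expect_equal(same$factor, 1)
  expect_equal(same$se, 0)
  # first-order propagation against a numeric-derivative oracle
  e <- as_summary_stat(11.8, se = 0.3); ne <- as_summary_stat(2.4, se = 0.1)
  got <- expansion_factor(e, ne)$se
  expect_equal(got, sqrt((0.3 / 2.4)^2 + (11.8 * 0.1 / 2.4^2)^2))
  expect_error(expansion_factor(1, 0), "positive")
})

test_that("spot intensity means first frames then subtracts background", {
  px <- array(1, dim = c(3, 40, 40))
  px[1, 1:14, 1:22] <- 900 / (14 * 22)
  px[2, 1:14, 1:22] <- 1000 / (14 * 22)
  px[3, 1:14, 1:22] <- 1100 / (14 * 22)
  px[, 20:33, 10:31] <- 200 / (14 * 22)
  stk <- image_stack(px)
  got <- spot_intensity(stk, list(row = 1, col = 1), list(row = 20, col = 10))
  expect_equal(got, 800)

  # linear in amplitude, invariant to a constant offset
  stk2 <- stk; stk2$pixels <- stk2$pixels + 50
  expect_equal(spot_intensity(stk2, list(row = 1, col = 1),
                              list(row = 20, col = 10)), 800)

  expect_error(spot_intensity(stk, list(row = 30, col = 30),
                              list(row = 1, col = 1)), "bounds")
  expect_warning(spot_intensity(stk, list(row = 1, col = 1, height = 10,
                                          width = 10),
                                list(row = 20, col = 10)), "14 x 22")
})

test_that("synthetic spot amplitudes are recovered to 2% by ROI integration", {
  stk <- simulate_spot_stack(matrix(c(20, 13) * 129, 1), 50000, 1.5,
                             background = 100, frames = 3, dim = c(40, 40),
                             noise = FALSE)
  got <- spot_intensity(stk, list(row = 7, col = 10), list(row = 25, col = 10))
  expect_equal(got, 50000, tolerance = 0.02)
})

test_that("retention yields are percentages of the reference step", {
  series <- retention_series(
    list(fixed = as_summary_stat(1000, se = 10),
         optimized = as_summary_stat(460, se = 12),
         proexm = as_summary_stat(220, se = 9)),
    reference = "fixed")
  y <- retention_yield(series)
  expect_equal(y$percent[y$step == "fixed"], 100)
  expect_equal(y$percent[y$step == "optimized"], 46)
  expect_equal(y$percent[y$step == "proexm"], 22)
  expect_error(retention_series(list(a = as_summary_stat(1)), "b"),
               "reference")
  expect_error(retention_yield(retention_series(
    list(a = as_summary_stat(0)), "a")), "positive")
})
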