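test_that("trajectory construction enforces its invariants", {
  expect_error(drift_trajectory(frame = 1:3, dx = 0:2, dy = 0:2),
               "frames 0")
  expect_error(drift_trajectory(frame = 0:2, dx = c(1, 2, 3), dy = 0:2),
               "zero at frame 0")
  tr <- drift_trajectory(0:2, c(0, 1, 2), c(0, -1, -2), support = 5)
  expect_s3_class(tr, "drift_trajectory")
})

test_that("cross-correlation reports near-zero drift on a drift-free movie", {
  sim <- marker_movie(9, frames = 1000, drift = drift_model("none"))
  tr <- drift_by_cross_correlation(sim$locs, substack_len = 250,
                                   render_px = 10)
  expect_lt(max(sqrt(tr$dx^2 + tr$dy^2)), 10)
})

test_that("cross-correlation resolves a constructed step displacement", {
  set.seed(4)
  mol <- sample_cell_points(default_geom(), 2000)
  idx <- sample(2000, 20000, TRUE)
  tab <- localizations(x = mol[idx, 1] + rnorm(20000, 0, 14),
                       y = mol[idx, 2] + rnorm(20000, 0, 14),
                       frame = sample(0:999, 20000, TRUE))
  sel <- tab$frame >= 500
  tab$x[sel] <- tab$x[sel] + 50
  tr <- drift_by_cross_correlation(tab, substack_len = 250, render_px = 10)
  # away from the interpolated boundary the two halves sit 50 nm apart in x
  expect_lt(abs(mean(tr$dx[1:400]) - 0), 5)
  expect_lt(abs(mean(tr$dx[601:1000]) - 50), 5)
  expect_lt(max(abs(tr$dy)), 10)
})

test_that("cross-correlation recovers a linear 1 nm/frame drift to within a bin", {
  sim <- marker_movie(1, drift = drift_model("linear", vx = 1, vy = 0))
  tr <- drift_by_cross_correlation(sim$locs, substack_len = 500,
                                   render_px = 10)
  expect_lt(traj_rmse(tr, sim$truth$drift), 10)
})

test_that("a single persistent emitter yields the exact frame-to-frame drift", {
  frames <- 0:99
  tab <- localizations(x = 1 * frames, y = 0 * frames, frame = frames)
  lt <- link_tracks(tab, max_dist = 10)
  tr <- drift_frame_to_frame(tab, lt$tracks, smooth_window = 0)
  expect_equal(tr$dx, as.numeric(frames), tolerance = 1e-12)
  expect_equal(tr$dy, rep(0, 100))
  expect_equal(tr$dx[100], 99)
})

test_that("frame-to-frame drift is null-calibrated on drift-free movies", {
  sim <- marker_movie(11, frames = 1000, n_molecules = 200,
                      drift = drift_model("none"))
  lt <- link_tracks(sim$locs, max_dist = 100)
  tr <- drift_frame_to_frame(sim$locs, lt$tracks)
  expect_lt(traj_rms(tr), 3 * 14 / sqrt(median(tr$support)))
})

test_that("fiducial drift correction is exact for noise-free markers", {
  frames <- 0:499
  path <- cbind(0.5 * frames, -0.2 * frames)
  seeds <- rbind(c(5000, 5000), c(8000, 2000))
  tab <- do.call(rbind, lapply(1:2, function(k) {
    data.frame(x = seeds[k, 1] + path[, 1], y = seeds[k, 2] + path[, 2],
               frame = frames)
  }))
  tr <- drift_from_fiducials(tab, seeds, radius = 500)
  expect_lt(max(abs(tr$dx - path[, 1])), 1e-9)
  expect_lt(max(abs(tr$dy - path[, 2])), 1e-9)

  # a constant offset between fiducial paths cancels
  tab2 <- tab
  shift <- tab2$frame >= 0 & rep(c(FALSE, TRUE), each = 500)
  tab2$x[shift] <- tab2$x[shift] + 300
  tr2 <- drift_from_fiducials(tab2, cbind(seeds[, 1] + c(0, 300), seeds[, 2]),
                              radius = 500)
  expect_lt(max(abs(tr2$dx - path[, 1])), 1e-9)
})

test_that("averaging noisy fiducials beats a single marker's precision", {
  set.seed(5)
  frames <- 0:499
  path <- cbind(0.5 * frames, -0.2 * frames)
  seeds <- rbind(c(5000, 5000), c(8000, 2000), c(2000, 8000))
  tab <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(x = seeds[k, 1] + path[, 1] + rnorm(500, 0, 10),
               y = seeds[k, 2] + path[, 2] + rnorm(500, 0, 10),
               frame = frames)
  }))
  tr <- drift_from_fiducials(tab, seeds, radius = 500)
  err2d <- sqrt(mean((tr$dx - path[, 1])^2 + (tr$dy - path[, 2])^2))
  expect_lt(err2d, 10)  # below the per-fiducial noise
  expect_error(drift_from_fiducials(tab, rbind(c(0, 0)), radius = 100),
               "50%")
})

test_that("drift application and correction are exact inverses", {
  sim <- simulate_cell(default_geom(),
                       sim_config(n_molecules = 200, frames = 100, seed = 3))
  tr <- drift_trajectory(0:99, c(0, cumsum(rep(0.7, 99))),
                         c(0, cumsum(rep(-0.3, 99))))
  zero <- drift_trajectory(0:99, rep(0, 100), rep(0, 100))
  expect_equal(apply_drift_correction(sim$locs, zero), sim$locs)
  round_trip <- apply_drift_correction(apply_drift(sim$locs, tr), tr)
  expect_equal(round_trip$x, sim$locs$x, tolerance = 1e-12)
  expect_equal(round_trip$y, sim$locs$y, tolerance = 1e-12)

  short <- drift_trajectory(0:10, rep(0, 11), rep(0, 11))
  expect_error(apply_drift_correction(sim$locs, short), "outside")
})

test_that("reliability assessment truncates movies at sustained support loss", {
  tr <- drift_trajectory(0:9, rep(0, 10), rep(0, 10),
                         support = c(10, 10, 10, 1, 0, 0, 0, 0, 0, 0))
  r <- assess_reliability(tr, min_support = 3, window = 1)
  expect_equal(r$last_frame, 2L)
  expect_false(r$empty)

  uniform <- drift_trajectory(0:9, rep(0, 10), rep(0, 10), support = 10)
  expect_equal(assess_reliability(uniform, 3, window = 1)$last_frame, 9L)

  none <- assess_reliability(tr, min_support = 20, window = 1)
  expect_true(none$empty)

  # photobleaching-style decay: reported range excludes the dim tail
  set.seed(6)
  decay <- drift_trajectory(0:199, rep(0, 200), rep(0, 200),
                            support = rpois(200, 20 * exp(-(0:199) / 40)))
  rd <- assess_reliability(decay, min_support = 3, window = 20)
  expect_false(rd$empty)
  expect_lt(rd$last_frame, 150L)
  expect_gt(rd$last_frame, 50L)
})
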