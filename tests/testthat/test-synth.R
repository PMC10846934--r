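test_that("noise-free, drift-free, unexpanded localizations coincide with molecules", {
  sim <- simulate_cell(default_geom(),
                       sim_config(n_molecules = 50, frames = 50,
                                  sigma_loc = 0, seed = 7))
  obs <- cbind(sim$locs$x, sim$locs$y)
  expect_gt(nrow(sim$locs), 0L)
  expect_equal(max(abs(obs - sim$truth$positions[sim$truth$molecule, ])), 0)
})

test_that("all molecule positions lie inside the declared geometry", {
  geom <- cell_geometry(length = 9000, width = 2400,
                        nucleus = nucleus_disk(diameter = 2360))
  pts <- sample_cell_points(geom, 1000, seed = 3)
  hl <- (geom$length - geom$width) / 2
  ax <- pmax(abs(pts[, 1]) - hl, 0)
  expect_true(all(ax^2 + pts[, 2]^2 <= (geom$width / 2)^2))
  # and outside the nucleus
  expect_true(all(pts[, 1]^2 + pts[, 2]^2 > (2360 / 2)^2))
})

test_that("simulation is reproducible under a fixed seed and varies across seeds", {
  cfg <- function(s) sim_config(n_molecules = 100, frames = 100, seed = s)
  a <- simulate_cell(default_geom(), cfg(42))
  b <- simulate_cell(default_geom(), cfg(42))
  c <- simulate_cell(default_geom(), cfg(43))
  expect_identical(a$locs, b$locs)
  expect_identical(a$truth$positions, b$truth$positions)
  expect_false(isTRUE(all.equal(a$locs, c$locs)))
})

test_that("degenerate configurations behave as specified", {
  empty <- simulate_cell(default_geom(),
                         sim_config(n_molecules = 0, frames = 100, seed = 1))
  expect_equal(nrow(empty$locs), 0L)
  expect_error(cell_geometry(length = 1000, width = 2400), "length >= width")
  expect_error(cell_geometry(nucleus = nucleus_disk(center = c(4000, 0))),
               "inside")
  expect_error(sim_config(expansion_factor = 0), "expansion_factor")
  expect_error(sim_config(sigma_loc = -1), ">= 0")
})

test_that("expansion without distortion scales every pairwise distance exactly", {
  set.seed(11)
  pts <- matrix(runif(60) * 5000, ncol = 2)
  expect_equal(apply_expansion(pts, 1), pts, ignore_attr = TRUE)
  two <- rbind(c(0, 0), c(100, 0))
  expect_equal(as.numeric(dist(apply_expansion(two, 4.9))), 490)
  for (f in c(0.5, 2.2, 4.9)) {
    ratio <- dist(apply_expansion(pts, f)) / dist(pts)
    expect_lt(max(abs(ratio - f) / f), 1e-9)
  }
  expect_error(apply_expansion(pts, 0), "factor")
})

test_that("distortion adds a zero-mean field of the requested RMS on top of scaling", {
  set.seed(12)
  pts <- sample_cell_points(default_geom(), 3000)
  pure <- apply_expansion(pts, 4.9)
  warped <- apply_expansion(pts, 4.9, distortion_amplitude = 200, seed = 5)
  resid <- warped - pure
  expect_equal(sqrt(mean(rowSums(resid^2))), 200, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(resid))), 1e-9)
  # pairwise distances still scale by ~4.9 on average
  i <- sample(3000, 500)
  expect_equal(mean(dist(warped[i, ]) / dist(pts[i, ])), 4.9,
               tolerance = 0.05)
  # reproducible
  expect_equal(apply_expansion(pts, 4.9, 200, seed = 5), warped,
               ignore_attr = TRUE)
})

test_that("emission counts match the configured mean localizations per molecule", {
  sim <- simulate_cell(default_geom(),
                       sim_config(n_molecules = 2000, frames = 1000,
                                  mean_locs_per_molecule = 3,
                                  on_time_frames = 1.5, seed = 21))
  per_mol <- tabulate(sim$truth$molecule, nbins = 2000)
  se <- sd(per_mol) / sqrt(2000)
  expect_lt(abs(mean(per_mol) - 3), 3 * se + 3 * 1.5 / (2 * 1000) * 3)
})

test_that("spot stacks conserve flux and render distinct sources", {
  stk <- simulate_spot_stack(matrix(c(32, 32) * 129, 1), 5000, 1.5,
                             background = 0, frames = 1, dim = c(64, 64),
                             noise = FALSE)
  expect_equal(sum(stk$pixels), 5000, tolerance = 0.005)
  with_bg <- simulate_spot_stack(matrix(c(32, 32) * 129, 1), 5000, 1.5,
                                 background = 10, frames = 1, dim = c(64, 64),
                                 noise = FALSE)
  expect_equal(sum(with_bg$pixels), 10 * 64 * 64 + 5000, tolerance = 0.005)

  two <- simulate_spot_stack(rbind(c(27, 32), c(37, 32)) * 129, 4000, 1.1,
                             background = 100, frames = 1, dim = c(64, 64),
                             noise = FALSE)
  img <- two$pixels[1, , ]
  row <- img[33, ]  # line through both spots
  local_max <- which(diff(sign(diff(row))) == -2) + 1L
  expect_equal(length(local_max), 2L)

  a <- simulate_spot_stack(matrix(c(32, 32) * 129, 1), 1000, 1.1, 50,
                           frames = 2, dim = c(32, 32), seed = 9)
  b <- simulate_spot_stack(matrix(c(32, 32) * 129, 1), 1000, 1.1, 50,
                           frames = 2, dim = c(32, 32), seed = 9)
  expect_identical(a$pixels, b$pixels)
  expect_error(simulate_spot_stack(matrix(0, 1, 2), -5, 1), ">= 0")
})

test_that("a rendered nuclear ring's peak-to-peak profile recovers its diameter", {
  # 2360 nm ring at 129 nm/px is 18.3 px across; measure the distance
  # between the two intensity peaks of the row through the centre
  ring <- ring_positions(center = c(32, 32) * 129, diameter = 2360, n = 180)
  stk <- simulate_spot_stack(ring, 1000, 1.1, background = 0, frames = 1,
                             dim = c(64, 64), noise = FALSE)
  img <- stk$pixels[1, , ]
  row <- img[33, ]
  centre_px <- 32
  left <- which.max(row[1:centre_px])
  right <- centre_px + which.max(row[(centre_px + 1):64])
  # peak pixel centres: separation in px
  sep_px <- (right - 0.5) - (left - 0.5)
  expect_equal(sep_px * 129, 2360, tolerance = 0.05)
})
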