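# Shared fixtures: everything is generated in code at test time.

default_geom <- function(...) cell_geometry(...)

# RMSE between an estimated and a true drift path (both per-frame).
traj_rmse <- function(est, true) {
  sqrt(mean((est$dx - true$dx)^2 + (est$dy - true$dy)^2))
}

traj_rms <- function(tr) sqrt(mean(tr$dx^2 + tr$dy^2))

# Photostable-marker movie: the configuration used for drift benchmarks
# (60 always-on emitters over 3000 frames gives >= 50 concurrent tracks).
marker_movie <- function(seed, frames = 3000, n_molecules = 60,
                         sigma_loc = 14,
                         drift = drift_model("both", vx = 0.08, vy = -0.05,
                                             step_sd = 0.3)) {
  simulate_cell(default_geom(),
                sim_config(n_molecules = n_molecules, frames = frames,
                           on_time_frames = Inf, sigma_loc = sigma_loc,
                           drift = drift, seed = seed))
}

# Blinking movie with deliberately fast drift for end-to-end NeNA checks.
blinking_movie <- function(seed, drift = drift_model("both", vx = 6, vy = -4,
                                                     step_sd = 3)) {
  simulate_cell(default_geom(),
                sim_config(n_molecules = 3000, frames = 600,
                           mean_locs_per_molecule = 3, on_time_frames = 1.5,
                           sigma_loc = 14, drift = drift, seed = seed))
}

# Point-set cells for the isotropy statistic (~2000 localizations per cell,
# the scale of the study's cytosolic marker cells).
make_cells <- function(n_cells, seed, n_points = 2000, factor = 1,
                       distortion = 0) {
  set.seed(seed)
  lapply(seq_len(n_cells), function(i) {
    p <- sample_cell_points(default_geom(), n_points)
    if (factor != 1 || distortion > 0) {
      p <- apply_expansion(p, factor, distortion_amplitude = distortion)
    }
    cell_point_set(p, expanded = factor != 1)
  })
}
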