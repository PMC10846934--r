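#' Describe a 2-D spherocylindrical cell
#'
#' Fission yeast cells are rod-shaped: in the single focal plane imaged
#' here they are well described by a 2-D spherocylinder (a rectangle
#' capped by two half-disks). Defaults follow the measured non-expanded
#' dimensions: cytosol width 2.4 um and nuclear diameter 2.36 um; the
#' default length of 9 um is a typical interphase cell length.
#'
#' @param length Cap-to-cap length in nm; must be >= `width`.
#' @param width Cell width (diameter of the caps) in nm.
#' @param center Numeric (x, y) centre in nm.
#' @param orientation Long-axis orientation in radians.
#' @param nucleus Optional list with elements `center` (x, y nm, relative
#'   to the cell centre along its axis frame) and `diameter` (nm); use
#'   `nucleus_disk()` for convenience. The nucleus must lie inside the
#'   cell.
#' @return An object of class `cell_geometry`.
#' @export
cell_geometry <- function(length = 9000, width = 2400, center = c(0, 0),
                          orientation = 0, nucleus = NULL) {
  if (!(length >= width) || !(width > 0)) {
    stop("cell geometry requires length >= width > 0", call. = FALSE)
  }
  geom <- structure(list(length = length, width = width,
                         center = as.numeric(center),
                         orientation = orientation, nucleus = nucleus),
                    class = "cell_geometry")
  if (!is.null(nucleus)) {
    r <- nucleus$diameter / 2
    # nucleus centre given in the cell's axis frame
    if (!in_spherocylinder(matrix(nucleus$center, 1), length, width,
                           margin = r)) {
      stop("nucleus does not lie inside the cell", call. = FALSE)
    }
  }
  geom
}

#' @rdname cell_geometry
#' @param diameter Nuclear diameter in nm.
#' @export
nucleus_disk <- function(center = c(0, 0), diameter = 2360) {
  list(center = as.numeric(center), diameter = diameter)
}

# Points (axis frame, cell centred at origin, long axis along x) inside a
# spherocylinder, optionally shrunk by `margin`.
in_spherocylinder <- function(pts, length, width, margin = 0) {
  hl <- (length - width) / 2
  r <- width / 2 - margin
  ax <- pmax(abs(pts[, 1]) - hl, 0)
  ax * ax + pts[, 2]^2 <= r * r
}

# Map axis-frame points to world coordinates and back.
axis_to_world <- function(pts, geom) {
  co <- cos(geom$orientation); si <- sin(geom$orientation)
  cbind(geom$center[1] + co * pts[, 1] - si * pts[, 2],
        geom$center[2] + si * pts[, 1] + co * pts[, 2])
}

#' Sample points uniformly over a cell interior
#'
#' Rejection-samples the spherocylinder interior, excluding the nuclear
#' disk when the geometry declares one (cytosolic markers are excluded
#' from the nucleus).
#'
#' @param geometry A [cell_geometry()].
#' @param n Number of points.
#' @param seed Optional RNG seed (`NULL` uses the current stream).
#' @return An n x 2 matrix of (x, y) positions in nm.
#' @export
sample_cell_points <- function(geometry, n, seed = NULL) {
  stopifnot(inherits(geometry, "cell_geometry"))
  with_seed(seed, {
    hl <- (geometry$length - geometry$width) / 2
    r <- geometry$width / 2
    pts <- matrix(numeric(0), 0, 2)
    while (nrow(pts) < n) {
      m <- max(2L * (n - nrow(pts)), 64L)
      cand <- cbind(stats::runif(m, -hl - r, hl + r),
                    stats::runif(m, -r, r))
      keep <- in_spherocylinder(cand, geometry$length, geometry$width)
      if (!is.null(geometry$nucleus)) {
        nc <- geometry$nucleus$center
        nr <- geometry$nucleus$diameter / 2
        keep <- keep &
          (cand[, 1] - nc[1])^2 + (cand[, 2] - nc[2])^2 > nr * nr
      }
      pts <- rbind(pts, cand[keep, , drop = FALSE])
    }
    axis_to_world(pts[seq_len(n), , drop = FALSE], geometry)
  })
}

#' Simulation configuration for synthetic PALM movies
#'
#' Bundles the photophysical, optical and mechanical parameters of a
#' simulated acquisition. Defaults emulate the study's non-expanded
#' cytosolic-mEos2 data: ~14 nm localization precision, short blinking
#' bursts with a mean of ~3 localizations per molecule, no drift, no
#' expansion.
#'
#' @param n_molecules Number of fluorophores.
#' @param frames Movie length in frames.
#' @param mean_locs_per_molecule Expected localizations per molecule
#'   (re-blinking allowed).
#' @param on_time_frames Geometric-mean burst length in frames; `Inf`
#'   makes every molecule visible in every frame (a photostable marker,
#'   useful for drift benchmarks).
#' @param sigma_loc Localization precision (per-axis Gaussian sd, nm);
#'   ~14 nm non-expanded, ~27 nm expanded in this study.
#' @param drift List describing stage drift, from [drift_model()].
#' @param expansion_factor Physical expansion applied to ground-truth
#'   positions (1 = non-expanded; ~4.9 for the expanded condition).
#' @param distortion_amplitude RMS magnitude (nm) of a smooth
#'   low-frequency displacement field applied after expansion
#'   (0 = perfectly isotropic expansion).
#' @param mean_intensity Mean photon count per localization.
#' @param seed RNG seed; a fixed seed makes [simulate_cell()] fully
#'   reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_molecules = 1000, frames = 1000,
                       mean_locs_per_molecule = 3, on_time_frames = 1.5,
                       sigma_loc = 14, drift = drift_model("none"),
                       expansion_factor = 1, distortion_amplitude = 0,
                       mean_intensity = 1000, seed = NULL) {
  if (n_molecules < 0 || frames < 0 || mean_locs_per_molecule < 0 ||
      sigma_loc < 0 || distortion_amplitude < 0) {
    stop("counts, sigma_loc and distortion_amplitude must be >= 0",
         call. = FALSE)
  }
  if (expansion_factor <= 0) {
    stop("expansion_factor must be > 0", call. = FALSE)
  }
  structure(list(n_molecules = n_molecules, frames = frames,
                 mean_locs_per_molecule = mean_locs_per_molecule,
                 on_time_frames = on_time_frames, sigma_loc = sigma_loc,
                 drift = drift, expansion_factor = expansion_factor,
                 distortion_amplitude = distortion_amplitude,
                 mean_intensity = mean_intensity, seed = seed),
            class = "sim_config")
}

#' Describe a stage-drift model
#'
#' @param type `"none"`, `"linear"`, `"random_walk"` or `"both"` (the sum
#'   of a linear and a random-walk component).
#' @param vx,vy Linear drift velocity, nm per frame.
#' @param step_sd Per-frame random-walk step sd, nm.
#' @return A list with class `drift_model`.
#' @export
drift_model <- function(type = c("none", "linear", "random_walk", "both"),
                        vx = 0, vy = 0, step_sd = 0) {
  type <- match.arg(type)
  if (type == "none") { vx <- 0; vy <- 0; step_sd <- 0 }
  if (type == "linear") step_sd <- 0
  if (type == "random_walk") { vx <- 0; vy <- 0 }
  structure(list(type = type, vx = vx, vy = vy, step_sd = step_sd),
            class = "drift_model")
}

#' Generate a per-frame drift path from a drift model
#'
#' @param model A [drift_model()].
#' @param frames Number of frames.
#' @param seed Optional RNG seed.
#' @return A data.frame with columns `frame`, `dx`, `dy` (nm relative to
#'   frame 0).
#' @export
simulate_drift_path <- function(model, frames, seed = NULL) {
  with_seed(seed, {
    f <- seq_len(frames) - 1L
    dx <- model$vx * f
    dy <- model$vy * f
    if (model$step_sd > 0 && frames > 1L) {
      dx <- dx + c(0, cumsum(stats::rnorm(frames - 1L, 0, model$step_sd)))
      dy <- dy + c(0, cumsum(stats::rnorm(frames - 1L, 0, model$step_sd)))
    }
    data.frame(frame = f, dx = dx, dy = dy)
  })
}

#' Expand a point set, optionally with a smooth distortion field
#'
#' Models the physical expansion of the gel: an isotropic scaling about
#' the point-cloud centroid (so all pairwise distances multiply exactly by
#' `factor`), optionally followed by a smooth, band-limited, zero-mean
#' displacement field of a requested RMS magnitude that emulates
#' non-uniform (anisotropic) expansion.
#'
#' The distortion field is a sum of K = 4 random sinusoidal plane-wave
#' modes per axis with wavelengths drawn between the minor and major
#' bounding-box extents of the scaled cloud: variation on a sub-cellular
#' scale, yet smooth at the scale of inter-molecular spacing. (A field
#' with wavelengths beyond the cell length would be locally affine, which
#' nearest-neighbour statistics cannot distinguish from an ideal
#' expansion.)
#'
#' @param points n x 2 matrix (or localization table) of positions, nm.
#' @param factor Expansion factor, > 0.
#' @param distortion_amplitude RMS displacement magnitude in nm (0
#'   disables distortion).
#' @param seed Optional RNG seed for the random field.
#' @param center Optional (x, y) scaling centre; defaults to the centroid.
#' @return The transformed n x 2 matrix, with the displacement field
#'   parameters attached as attribute `"distortion_field"` when
#'   distortion is active.
#' @export
apply_expansion <- function(points, factor, distortion_amplitude = 0,
                            seed = NULL, center = NULL) {
  if (factor <= 0) stop("expansion factor must be > 0", call. = FALSE)
  pts <- as_points(points)
  if (nrow(pts) == 0L) return(pts)
  if (is.null(center)) center <- colMeans(pts)
  out <- sweep(sweep(pts, 2, center) * factor, 2, center, "+")
  if (distortion_amplitude > 0 && nrow(out) > 1L) {
    field <- with_seed(seed, random_distortion_field(out))
    disp <- eval_distortion_field(field, out)
    # centre and rescale so the realized field is zero-mean with the
    # requested RMS magnitude over these points
    disp <- sweep(disp, 2, colMeans(disp))
    rms <- sqrt(mean(rowSums(disp^2)))
    if (rms > 0) disp <- disp * (distortion_amplitude / rms)
    out <- out + disp
    attr(out, "distortion_field") <- field
  }
  colnames(out) <- c("x", "y")
  out
}

# Draw random plane-wave modes for the distortion field; wavelengths span
# the bounding-box extents of the point cloud.
random_distortion_field <- function(pts, n_modes = 4L) {
  ext <- sort(c(diff(range(pts[, 1])), diff(range(pts[, 2]))))
  lam <- stats::runif(2L * n_modes, ext[1], ext[2])
  theta <- stats::runif(2L * n_modes, 0, 2 * pi)
  phase <- stats::runif(2L * n_modes, 0, 2 * pi)
  weight <- stats::rnorm(2L * n_modes)
  list(n_modes = n_modes, lambda = lam, theta = theta, phase = phase,
       weight = weight)
}

eval_distortion_field <- function(field, pts) {
  K <- field$n_modes
  disp <- matrix(0, nrow(pts), 2)
  for (j in seq_len(2L * K)) {
    axis <- if (j <= K) 1L else 2L
    k <- 2 * pi / field$lambda[j]
    kx <- cos(field$theta[j]) * k
    ky <- sin(field$theta[j]) * k
    disp[, axis] <- disp[, axis] +
      field$weight[j] * sin(kx * pts[, 1] + ky * pts[, 2] + field$phase[j])
  }
  disp
}

#' Simulate a PALM acquisition of one cell
#'
#' Generates ground-truth molecule positions uniformly over the cell
#' interior (excluding the nucleus if configured), applies the expansion
#' transform, draws a blinking schedule per molecule (a geometric number
#' of frame-contiguous bursts of geometric length, started uniformly over
#' the movie), and emits observed localizations
#'
#' \deqn{obs = expanded\ position + drift(frame) + N(0, \sigma_{loc}^2)}
#'
#' Drift is shared by all molecules of a frame and applied only to the
#' observations, never to the ground truth, mirroring physical stage
#' drift.
#'
#' @param geometry A [cell_geometry()].
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{`truth`}{ground truth: `positions` (post-expansion,
#'       post-distortion molecule positions), `molecule` (per-localization
#'       molecule index), `drift` (true per-frame path), and the applied
#'       `expansion_factor`.}
#'     \item{`locs`}{the observed localization table.}
#'   }
#' @export
simulate_cell <- function(geometry, config) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_mol <- config$n_molecules
    mol_true <- sample_cell_points(geometry, n_mol)
    mol_pos <- apply_expansion(mol_true, config$expansion_factor,
                               config$distortion_amplitude,
                               center = geometry$center)
    sched <- blink_schedule(n_mol, config)
    drift_path <- simulate_drift_path(config$drift, config$frames)
    n <- length(sched$molecule)
    if (n == 0L) {
      locs <- localizations()
    } else {
      noise_x <- stats::rnorm(n, 0, config$sigma_loc)
      noise_y <- stats::rnorm(n, 0, config$sigma_loc)
      fr <- sched$frame
      locs <- localizations(
        x = mol_pos[sched$molecule, 1] + drift_path$dx[fr + 1L] + noise_x,
        y = mol_pos[sched$molecule, 2] + drift_path$dy[fr + 1L] + noise_y,
        frame = fr,
        intensity = stats::rgamma(n, shape = 2,
                                  scale = config$mean_intensity / 2))
      ord <- order(locs$frame)
      locs <- locs[ord, , drop = FALSE]
      rownames(locs) <- NULL
      sched$molecule <- sched$molecule[ord]
    }
    list(truth = list(positions = mol_pos, molecule = sched$molecule,
                      drift = drift_path,
                      expansion_factor = config$expansion_factor,
                      distortion_field = attr(mol_pos, "distortion_field")),
         locs = locs)
  })
}

# Draw the per-molecule blinking schedule: returns per-localization
# molecule index and frame, unsorted.
blink_schedule <- function(n_mol, config) {
  frames <- config$frames
  if (n_mol == 0L || frames == 0L || config$mean_locs_per_molecule == 0) {
    return(list(molecule = integer(0), frame = integer(0)))
  }
  if (is.infinite(config$on_time_frames)) {
    # photostable marker: every molecule visible in every frame
    return(list(molecule = rep(seq_len(n_mol), each = frames),
                frame = rep(seq_len(frames) - 1L, times = n_mol)))
  }
  burst_mean <- max(1, min(config$on_time_frames,
                           config$mean_locs_per_molecule))
  bursts_mean <- max(1, config$mean_locs_per_molecule / burst_mean)
  n_bursts <- 1L + stats::rgeom(n_mol, 1 / bursts_mean)
  mol <- rep(seq_len(n_mol), n_bursts)
  nb <- length(mol)
  len <- 1L + stats::rgeom(nb, 1 / burst_mean)
  start <- sample.int(frames, nb, replace = TRUE) - 1L
  len <- pmin(len, frames - start)
  list(molecule = rep(mol, len),
       frame = unlist(lapply(seq_len(nb), function(i) {
         start[i] + seq_len(len[i]) - 1L
       }), use.names = FALSE))
}

#' Positions on a circle, for ring-shaped sources
#'
#' Convenience for building the nuclear-envelope (Nup132-style) ring used
#' in diameter assays: `n` point sources evenly spaced on a circle.
#'
#' @param center (x, y) in nm.
#' @param diameter Ring diameter in nm.
#' @param n Number of sources.
#' @return An n x 2 matrix of positions, nm.
#' @export
ring_positions <- function(center = c(0, 0), diameter = 2360, n = 64L) {
  a <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1] + diameter / 2 * cos(a),
        y = center[2] + diameter / 2 * sin(a))
}

#' Simulate a diffraction-limited spot image stack
#'
#' Renders point sources as integrated 2-D Gaussians (the flux of each
#' source inside a pixel is the product of the Gaussian integrals over the
#' pixel's x and y ranges, so total flux is conserved up to raster
#' truncation) on a constant background, optionally with Poisson shot
#' noise. Used for the spot-intensity retention assay and, with
#' [ring_positions()], for nuclear-diameter images.
#'
#' @param spot_positions n x 2 matrix of source positions, nm.
#' @param amplitudes Integrated intensity per source (photons); recycled.
#' @param psf_sigma_px PSF standard deviation in pixels.
#' @param background Constant background level per pixel.
#' @param frames Number of identical-statistics frames to render.
#' @param dim Image size as (rows, cols) in pixels.
#' @param pixel_size nm per pixel (camera default 129).
#' @param noise Add Poisson shot noise? (`FALSE` renders the noiseless
#'   expectation.)
#' @param seed Optional RNG seed.
#' @return An [image_stack()].
#' @export
simulate_spot_stack <- function(spot_positions, amplitudes, psf_sigma_px,
                                background = 0, frames = 3L,
                                dim = c(64L, 64L), pixel_size = 129,
                                noise = TRUE, seed = NULL) {
  pos <- as_points(spot_positions)
  amplitudes <- rep_len(as.numeric(amplitudes), nrow(pos))
  if (any(amplitudes < 0)) {
    stop("spot amplitudes must be >= 0", call. = FALSE)
  }
  nr <- dim[1]; nc <- dim[2]
  base <- matrix(background, nr, nc)
  s <- psf_sigma_px
  for (i in seq_len(nrow(pos))) {
    cx <- pos[i, 1] / pixel_size  # in pixel units, origin at pixel corner
    cy <- pos[i, 2] / pixel_size
    fx <- diff(stats::pnorm(0:nc, mean = cx, sd = s))
    fy <- diff(stats::pnorm(0:nr, mean = cy, sd = s))
    base <- base + amplitudes[i] * outer(fy, fx)
  }
  px <- array(0, dim = c(frames, nr, nc))
  with_seed(seed, {
    for (f in seq_len(frames)) {
      px[f, , ] <- if (noise) {
        matrix(stats::rpois(nr * nc, lambda = base), nr, nc)
      } else {
        base
      }
    }
  })
  image_stack(px, pixel_size = pixel_size)
}
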