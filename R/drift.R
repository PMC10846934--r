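#' Construct a drift trajectory
#'
#' A drift trajectory records the apparent per-frame motion of the sample
#' relative to frame 0, plus a per-frame support count (how many
#' observations — track links, localizations or fiducials — informed that
#' frame's estimate). Correction subtracts the trajectory from the data.
#'
#' @param frame 0-based frame indices, contiguous from 0.
#' @param dx,dy Displacement in nm relative to frame 0.
#' @param support Per-frame count of contributing observations.
#' @param method Label of the estimator that produced it.
#' @return A `data.frame` with class `drift_trajectory`.
#' @export
drift_trajectory <- function(frame, dx, dy, support = NA_real_,
                             method = "unspecified") {
  df <- data.frame(frame = as.integer(frame), dx = as.numeric(dx),
                   dy = as.numeric(dy), support = as.numeric(support))
  if (nrow(df) > 0L) {
    if (df$frame[1] != 0L || any(diff(df$frame) != 1L)) {
      stop("trajectory must cover frames 0..N-1 contiguously", call. = FALSE)
    }
    if (abs(df$dx[1]) > 1e-9 || abs(df$dy[1]) > 1e-9) {
      stop("trajectory must be zero at frame 0", call. = FALSE)
    }
  }
  class(df) <- c("drift_trajectory", "data.frame")
  attr(df, "method") <- method
  df
}

# Piecewise-linear interpolation over anchor frames with *linear*
# extrapolation from the first/last anchor pairs, evaluated at 0..n-1.
interp_anchors <- function(anchor_f, anchor_v, n_frames) {
  f <- seq_len(n_frames) - 1
  if (length(anchor_f) == 1L) return(rep(anchor_v, n_frames))
  v <- stats::approx(anchor_f, anchor_v, xout = f, rule = 2)$y
  k <- length(anchor_f)
  lo <- f < anchor_f[1]
  hi <- f > anchor_f[k]
  if (any(lo)) {
    sl <- (anchor_v[2] - anchor_v[1]) / (anchor_f[2] - anchor_f[1])
    v[lo] <- anchor_v[1] + sl * (f[lo] - anchor_f[1])
  }
  if (any(hi)) {
    sl <- (anchor_v[k] - anchor_v[k - 1]) / (anchor_f[k] - anchor_f[k - 1])
    v[hi] <- anchor_v[k] + sl * (f[hi] - anchor_f[k])
  }
  v
}

#' Estimate drift by sub-stack cross-correlation
#'
#' Splits the movie into temporal sub-stacks, renders each as a 2-D
#' localization histogram on a common grid, and measures the translation
#' of every sub-stack image against the first by phase-free
#' cross-correlation with sub-pixel refinement (3x3 intensity centroid
#' around the correlation maximum). Each offset is anchored at its
#' sub-stack's central frame; per-frame values are obtained by linear
#' interpolation between anchors (and linear extrapolation beyond the
#' first/last anchors, so a steady drift is tracked to the movie ends).
#'
#' This is the method of choice when localization density is high (e.g.
#' abundant cytosolic marker molecules); at low densities prefer
#' [drift_frame_to_frame()].
#'
#' @param table A localization table.
#' @param substack_len Frames per sub-stack (default 500).
#' @param render_px Histogram bin size in nm (default 10); also the
#'   scale of the method's accuracy.
#' @return A [drift_trajectory()]; per-frame `support` is the number of
#'   localizations in that frame (0-support frames were interpolated).
#' @export
drift_by_cross_correlation <- function(table, substack_len = 500L,
                                       render_px = 10) {
  validate_localizations(table)
  if (nrow(table) == 0L) stop("empty localization table", call. = FALSE)
  n_frames <- max(table$frame) + 1L
  sub <- table$frame %/% substack_len
  n_sub <- max(sub) + 1L
  # common histogram grid over the full table
  cx0 <- floor(min(table$x) / render_px)
  cy0 <- floor(min(table$y) / render_px)
  nx <- floor(max(table$x) / render_px) - cx0 + 1L
  ny <- floor(max(table$y) / render_px) - cy0 + 1L
  bins_x <- floor(table$x / render_px) - cx0 + 1L
  bins_y <- floor(table$y / render_px) - cy0 + 1L
  imgs <- vector("list", n_sub)
  counts <- integer(n_sub)
  for (s in seq_len(n_sub)) {
    in_s <- sub == s - 1L
    counts[s] <- sum(in_s)
    if (counts[s] > 0L) {
      m <- matrix(0, ny, nx)
      tab <- table(factor(bins_y[in_s], levels = seq_len(ny)),
                   factor(bins_x[in_s], levels = seq_len(nx)))
      imgs[[s]] <- m + as.numeric(tab)
    }
  }
  nonempty <- which(counts > 0L)
  if (length(nonempty) < 2L) {
    stop("need at least two sub-stacks with localizations", call. = FALSE)
  }
  ref <- imgs[[nonempty[1]]]
  anchors_f <- numeric(0); anchors_dx <- numeric(0); anchors_dy <- numeric(0)
  for (s in nonempty) {
    off <- xcorr_offset(ref, imgs[[s]])
    f0 <- (s - 1L) * substack_len
    f1 <- min(s * substack_len, n_frames) - 1L
    anchors_f <- c(anchors_f, (f0 + f1) / 2)
    anchors_dx <- c(anchors_dx, off[1] * render_px)
    anchors_dy <- c(anchors_dy, off[2] * render_px)
  }
  dx <- interp_anchors(anchors_f, anchors_dx, n_frames)
  dy <- interp_anchors(anchors_f, anchors_dy, n_frames)
  support <- tabulate(table$frame + 1L, nbins = n_frames)
  drift_trajectory(seq_len(n_frames) - 1L, dx - dx[1], dy - dy[1],
                   support, method = "cross_correlation")
}

# Translation (dx, dy) in pixels of image B relative to reference A,
# via FFT cross-correlation with a 3x3 centroid around the peak.
xcorr_offset <- function(A, B) {
  FA <- stats::fft(A)
  FB <- stats::fft(B)
  C <- Re(stats::fft(Conj(FA) * FB, inverse = TRUE))
  ny <- nrow(C); nx <- ncol(C)
  pk <- which.max(C)
  pr <- (pk - 1L) %% ny + 1L
  pc <- (pk - 1L) %/% ny + 1L
  # 3x3 neighbourhood with circular wrap
  rr <- ((pr - 2L):(pr)) %% ny + 1L
  cc <- ((pc - 2L):(pc)) %% nx + 1L
  W <- C[rr, cc]
  W <- W - min(W)
  if (sum(W) <= 0) W <- W + 1
  dr <- sum(W * matrix(-1:1, 3, 3)) / sum(W)
  dc <- sum(W * matrix(-1:1, 3, 3, byrow = TRUE)) / sum(W)
  sr <- pr - 1 + dr
  sc <- pc - 1 + dc
  if (sr > ny / 2) sr <- sr - ny
  if (sc > nx / 2) sc <- sc - nx
  c(dx = sc, dy = sr)
}

#' Estimate drift from tracked data by relative frame-to-frame shifts
#'
#' For every consecutive frame pair (t, t+1) the shift is the mean
#' displacement over all track links spanning exactly that pair; pairs
#' without links contribute zero shift (with support 0). The cumulative
#' sum of the pairwise shifts gives the trajectory, which is then smoothed
#' by a centred moving average and re-anchored to zero at frame 0.
#'
#' Because the per-track errors telescope along a track's lifetime, this
#' estimator remains accurate over long movies whenever a few tens of
#' concurrent tracks are available — the regime of the cytosolic-marker
#' cells mixed into every sample for this purpose.
#'
#' @param table A localization table.
#' @param tracks Tracks over `table` from [link_tracks()].
#' @param smooth_window Centred moving-average window in frames (odd;
#'   default 11; 0 or 1 disables smoothing).
#' @return A [drift_trajectory()]; `support` counts the links that
#'   produced each frame's incremental shift.
#' @export
drift_frame_to_frame <- function(table, tracks, smooth_window = 11L) {
  validate_localizations(table)
  if (length(tracks) == 0L || all(track_steps(tracks) == 0L)) {
    stop("no tracked support for drift estimation", call. = FALSE)
  }
  n_frames <- max(table$frame) + 1L
  # collect all adjacent-frame links across tracks
  from <- integer(0); to <- integer(0)
  for (ix in tracks) {
    if (length(ix) < 2L) next
    adj <- which(diff(table$frame[ix]) == 1L)
    from <- c(from, ix[adj])
    to <- c(to, ix[adj + 1L])
  }
  if (length(from) == 0L) {
    stop("no tracked support for drift estimation", call. = FALSE)
  }
  pair <- table$frame[from] + 1L  # pair t -> t+1 indexed by t+1 in 1..n-1
  ddx <- table$x[to] - table$x[from]
  ddy <- table$y[to] - table$y[from]
  n_pairs <- n_frames - 1L
  cnt <- tabulate(pair, nbins = n_pairs)
  sx <- rep(0, n_pairs); sy <- rep(0, n_pairs)
  agg_x <- tapply(ddx, pair, sum)
  agg_y <- tapply(ddy, pair, sum)
  at <- as.integer(names(agg_x))
  sx[at] <- agg_x / cnt[at]
  sy[at] <- agg_y / cnt[at]
  dx <- c(0, cumsum(sx))
  dy <- c(0, cumsum(sy))
  if (smooth_window > 1L) {
    dx <- moving_average(dx, smooth_window)
    dy <- moving_average(dy, smooth_window)
  }
  drift_trajectory(seq_len(n_frames) - 1L, dx - dx[1], dy - dy[1],
                   support = c(cnt[1], cnt),
                   method = "frame_to_frame")
}

#' Estimate drift from fiducial markers
#'
#' Each fiducial is followed as the nearest localization within `radius`
#' of its seed position in every frame; its per-frame displacement from
#' its own frame-0 position reports the drift, and the trajectory is the
#' mean over fiducials. Frames in which a fiducial is missing use the
#' remaining fiducials; frames with none are linearly interpolated.
#' Fiducials localized in fewer than half of all frames are rejected.
#'
#' @param table A localization table.
#' @param fiducial_positions k x 2 matrix of approximate (seed) fiducial
#'   positions, nm.
#' @param radius Search radius around each seed, nm.
#' @return A [drift_trajectory()]; `support` is the number of fiducials
#'   contributing per frame.
#' @export
drift_from_fiducials <- function(table, fiducial_positions, radius) {
  validate_localizations(table)
  seeds <- as_points(fiducial_positions)
  if (nrow(seeds) == 0L) stop("at least one fiducial required", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  n_frames <- max(table$frame) + 1L
  by_frame <- split(seq_len(nrow(table)), table$frame)
  paths <- vector("list", nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    px <- rep(NA_real_, n_frames); py <- rep(NA_real_, n_frames)
    for (fname in names(by_frame)) {
      ix <- by_frame[[fname]]
      d2 <- (table$x[ix] - seeds[k, 1])^2 + (table$y[ix] - seeds[k, 2])^2
      j <- which.min(d2)
      if (length(j) == 1L && d2[j] <= radius^2) {
        f <- as.integer(fname) + 1L
        px[f] <- table$x[ix[j]]; py[f] <- table$y[ix[j]]
      }
    }
    if (mean(!is.na(px)) >= 0.5) {
      # displacement relative to this fiducial's first observed position
      ref <- which(!is.na(px))[1]
      paths[[k]] <- cbind(px - px[ref], py - py[ref])
    }
  }
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (length(paths) == 0L) {
    stop("no fiducial is localized in at least 50% of frames within radius",
         call. = FALSE)
  }
  arr_x <- sapply(paths, function(p) p[, 1])
  arr_y <- sapply(paths, function(p) p[, 2])
  support <- rowSums(!is.na(arr_x))
  dx <- rowMeans(arr_x, na.rm = TRUE)
  dy <- rowMeans(arr_y, na.rm = TRUE)
  fill <- function(v) {
    if (all(is.na(v))) stop("no fiducial coverage at all", call. = FALSE)
    if (anyNA(v)) {
      idx <- which(!is.na(v))
      v <- interp_anchors(idx - 1, v[idx], length(v))
    }
    v
  }
  dx <- fill(dx); dy <- fill(dy)
  drift_trajectory(seq_len(n_frames) - 1L, dx - dx[1], dy - dy[1],
                   support, method = "fiducial")
}

#' Apply or remove a drift trajectory
#'
#' `apply_drift_correction()` subtracts the trajectory from each
#' localization's position (the trajectory is the apparent motion of the
#' sample); `apply_drift()` adds it, e.g. to inject known drift into
#' synthetic data. The two are exact inverses.
#'
#' @param table A localization table.
#' @param trajectory A [drift_trajectory()] covering every frame present
#'   in `table`.
#' @return The corrected (or drifted) localization table.
#' @export
apply_drift_correction <- function(table, trajectory) {
  shift_by_trajectory(table, trajectory, -1)
}

#' @rdname apply_drift_correction
#' @export
apply_drift <- function(table, trajectory) {
  shift_by_trajectory(table, trajectory, +1)
}

shift_by_trajectory <- function(table, trajectory, sign) {
  validate_localizations(table)
  if (nrow(table) == 0L) return(table)
  pos <- match(table$frame, trajectory$frame)
  if (anyNA(pos)) {
    stop(sprintf("frame %d is outside the trajectory's domain",
                 table$frame[which(is.na(pos))[1]]), call. = FALSE)
  }
  out <- table
  out$x <- table$x + sign * trajectory$dx[pos]
  out$y <- table$y + sign * trajectory$dy[pos]
  out
}

#' Find the reliably drift-corrected frame range
#'
#' Drift estimates degrade when localization density decays (typically at
#' the end of a PALM movie, through photobleaching); such data should be
#' discarded. This returns the longest prefix of the movie over which a
#' trailing-window mean of the trajectory's support stays at or above
#' `min_support`.
#'
#' @param trajectory A [drift_trajectory()].
#' @param min_support Minimum acceptable trailing-window mean support.
#' @param window Trailing window length in frames (default 50).
#' @return A list with `first_frame`, `last_frame` (0-based, inclusive)
#'   and `empty` (`TRUE` when no frame qualifies; then the frame fields
#'   are `NA`).
#' @export
assess_reliability <- function(trajectory, min_support, window = 50L) {
  s <- trajectory$support
  n <- length(s)
  cs <- cumsum(c(0, s))
  lo <- pmax(seq_len(n) - window + 1L, 1L)
  m <- (cs[seq_len(n) + 1L] - cs[lo]) / (seq_len(n) - lo + 1L)
  ok <- m >= min_support
  if (n == 0L || !ok[1]) {
    return(list(first_frame = NA_integer_, last_frame = NA_integer_,
                empty = TRUE))
  }
  last <- if (all(ok)) n else which(!ok)[1] - 1L
  list(first_frame = 0L, last_frame = as.integer(last - 1L), empty = FALSE)
}
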