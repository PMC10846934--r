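#' Link localizations into blink tracks
#'
#' Greedy frame-ordered nearest-neighbour linking, the behaviour of
#' typical SMLM trackers at the sparse emitter densities where it is
#' applied: frames are processed in order, and each active track claims
#' the nearest unclaimed localization within `max_dist`, allowing a
#' blinking gap of up to `max_gap` frames between consecutive detections
#' (the study's tracking used a five-frame blinking interval). Conflicts
#' are resolved by smaller distance, then lower localization row index,
#' then older track. Every localization ends up in exactly one track;
#' unclaimed localizations start new tracks (a lone detection is a 0-step
#' track).
#'
#' @param table A localization table.
#' @param max_dist Maximum linking distance in nm; a practical choice is
#'   ~3x the expected localization precision.
#' @param max_gap Maximum frame difference between consecutive detections
#'   of one track (default 5).
#' @return A list with elements
#'   \describe{
#'     \item{`tracks`}{list of integer vectors of row indices into
#'       `table`, each ordered by frame;}
#'     \item{`table`}{the input table with a `track_id` column added.}
#'   }
#' @export
link_tracks <- function(table, max_dist, max_gap = 5L) {
  validate_localizations(table)
  if (max_dist <= 0) stop("max_dist must be > 0", call. = FALSE)
  if (max_gap < 1) stop("max_gap must be >= 1", call. = FALSE)
  n <- nrow(table)
  track_of <- integer(n)
  if (n > 0L) {
    x <- table$x; y <- table$y; fr <- table$frame
    n_tracks <- 0L
    # open-track state, indexed by track id
    last_x <- numeric(0); last_y <- numeric(0); last_f <- integer(0)
    frames_present <- sort(unique(fr))
    by_frame <- split(seq_len(n), fr)[as.character(frames_present)]
    for (fi in seq_along(frames_present)) {
      f <- frames_present[fi]
      idx <- by_frame[[fi]][order(by_frame[[fi]])]
      active <- which(last_f >= f - max_gap & last_f < f)
      claimed <- rep(FALSE, length(idx))
      if (length(active) > 0L) {
        d <- cross_dist(cbind(last_x[active], last_y[active]),
                        cbind(x[idx], y[idx]))
        ok <- which(d <= max_dist)
        if (length(ok) > 0L) {
          rowi <- (ok - 1L) %% length(active) + 1L
          coli <- (ok - 1L) %/% length(active) + 1L
          # greedy order: distance, then localization index, then track age
          ord <- order(d[ok], idx[coli], active[rowi])
          used_tr <- rep(FALSE, length(active))
          for (k in ord) {
            if (used_tr[rowi[k]] || claimed[coli[k]]) next
            tr <- active[rowi[k]]
            j <- idx[coli[k]]
            track_of[j] <- tr
            last_x[tr] <- x[j]; last_y[tr] <- y[j]; last_f[tr] <- f
            used_tr[rowi[k]] <- TRUE
            claimed[coli[k]] <- TRUE
          }
        }
      }
      for (j in idx[!claimed]) {
        n_tracks <- n_tracks + 1L
        track_of[j] <- n_tracks
        last_x[n_tracks] <- x[j]; last_y[n_tracks] <- y[j]
        last_f[n_tracks] <- f
      }
    }
  }
  tracks <- split(seq_len(n), track_of)
  tracks <- unname(tracks[order(as.integer(names(tracks)))])
  tracks <- lapply(tracks, function(ix) ix[order(table$frame[ix], ix)])
  out <- table
  out$track_id <- track_of
  list(tracks = tracks, table = out)
}

#' Number of steps (inter-detection links) per track
#'
#' @param tracks List of tracks as returned by [link_tracks()].
#' @return Integer vector of step counts (`detections - 1`).
#' @export
track_steps <- function(tracks) {
  vapply(tracks, function(ix) length(ix) - 1L, integer(1))
}

#' Drop short trajectories
#'
#' Retains tracks with at least `min_steps` inter-detection links. The
#' default 4 implements the rule of discarding all trajectories of three
#' steps and less (a 4-step track has at least five detections).
#'
#' @inheritParams track_steps
#' @param min_steps Minimum number of links for a track to be kept.
#' @return The filtered list of tracks.
#' @export
filter_tracks <- function(tracks, min_steps = 4L) {
  tracks[track_steps(tracks) >= min_steps]
}

#' Merge the localizations of each track into one
#'
#' Combines multiple localizations of the same fluorescence event into a
#' single record: intensity-weighted mean position, first frame, summed
#' intensity. Without an intensity column the position is the unweighted
#' centroid.
#'
#' @param table A localization table.
#' @param tracks A list of tracks partitioning `table` (from
#'   [link_tracks()], possibly filtered).
#' @return A localization table with one row per track.
#' @export
merge_track_localizations <- function(table, tracks) {
  validate_localizations(table)
  has_int <- "intensity" %in% names(table)
  rows <- lapply(seq_along(tracks), function(ti) {
    ix <- tracks[[ti]]
    w <- if (has_int) table$intensity[ix] else rep(1, length(ix))
    if (sum(w) <= 0) w <- rep(1, length(ix))
    data.frame(x = sum(table$x[ix] * w) / sum(w),
               y = sum(table$y[ix] * w) / sum(w),
               frame = min(table$frame[ix]),
               intensity = if (has_int) sum(table$intensity[ix]) else NA_real_,
               track_id = ti)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- localizations(intensity = numeric(0), track_id = integer(0))
  }
  if (!has_int) out$intensity <- NULL
  validate_localizations(out)
  out
}
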