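#' Construct a localization table
#'
#' A localization table is the central data structure of the package: one
#' row per detected single-molecule event, with continuous coordinates in
#' nanometres and a 0-based acquisition frame index. It is an ordinary
#' `data.frame`, so all of R's data-manipulation tools apply.
#'
#' Coordinates live in a Cartesian frame whose origin is the top-left
#' corner of camera pixel (0,0); the centre of raster pixel (r,c) at pixel
#' size p is at ((c+0.5)p, (r+0.5)p). Frames are 0-based and treated as
#' half-open ranges throughout the package.
#'
#' @param x,y Numeric, position in nm.
#' @param frame Integer-valued, 0-based frame index.
#' @param intensity Optional numeric, photon count or ADU (any unit, as
#'   long as it is used consistently).
#' @param track_id Optional integer, assigned by [link_tracks()].
#' @return A `data.frame` with columns `x`, `y`, `frame` and, when
#'   supplied, `intensity` and `track_id`.
#' @seealso [read_localizations()], [write_localizations()]
#' @export
#' @examples
#' locs <- localizations(x = c(100, 110), y = c(50, 52), frame = c(0, 1))
localizations <- function(x = numeric(), y = numeric(), frame = integer(),
                          intensity = NULL, track_id = NULL) {
  df <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   frame = as.integer(frame))
  if (!is.null(intensity)) df$intensity <- as.numeric(intensity)
  if (!is.null(track_id)) df$track_id <- as.integer(track_id)
  validate_localizations(df)
  df
}

#' Validate a localization table
#'
#' Checks the structural invariants every module relies on: mandatory
#' columns `x`, `y`, `frame`; finite coordinates; non-negative integer
#' frames. An empty table is valid.
#'
#' @param table A data.frame of localizations.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_localizations <- function(table) {
  if (!is.data.frame(table)) {
    stop("localization table must be a data.frame", call. = FALSE)
  }
  for (col in c("x", "y", "frame")) {
    if (!col %in% names(table)) {
      stop(sprintf("localization table is missing mandatory column '%s'", col),
           call. = FALSE)
    }
  }
  if (nrow(table) > 0L) {
    if (!all(is.finite(table$x)) || !all(is.finite(table$y))) {
      stop("localization coordinates must be finite", call. = FALSE)
    }
    fr <- table$frame
    if (any(!is.finite(fr)) || any(fr < 0) || any(fr != floor(fr))) {
      stop("frame indices must be non-negative integers", call. = FALSE)
    }
  }
  invisible(table)
}

# Canonical column order for serialization.
loc_columns <- function(table) {
  intersect(c("x", "y", "frame", "intensity", "track_id"), names(table))
}
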