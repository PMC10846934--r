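# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. `seed = NULL` evaluates in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Coerce a points argument (2-column matrix/data.frame or localization
# table with x/y columns) to an n x 2 numeric matrix.
as_points <- function(points) {
  if (is.data.frame(points)) {
    if (all(c("x", "y") %in% names(points))) {
      points <- cbind(points$x, points$y)
    } else {
      points <- as.matrix(points)
    }
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) {
    stop("points must have two columns (x, y)", call. = FALSE)
  }
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  points
}

# Euclidean cross-distance matrix between two point sets (rows of a, b).
cross_dist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

# Centred moving average with shrinking windows at the ends, so the output
# is defined for every input position. `window` must be odd; 0 or 1 is the
# identity.
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 0L) return(x)
  if (window %% 2L == 0L) stop("smoothing window must be odd", call. = FALSE)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
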