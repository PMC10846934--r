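#' Nearest-neighbour distances between adjacent frames
#'
#' For every localization in frame t, the Euclidean distance to its
#' nearest neighbour in frame t+1 (localizations whose next frame is
#' empty contribute nothing). Because a blinking molecule is frequently
#' re-detected in consecutive frames, the small-distance part of this
#' distribution carries the localization precision.
#'
#' @param table A localization table with at least two frames.
#' @return Numeric vector of distances, nm.
#' @export
adjacent_frame_nn_distances <- function(table) {
  validate_localizations(table)
  by_frame <- split(seq_len(nrow(table)), table$frame)
  frames <- as.integer(names(by_frame))
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    j <- match(frames[i] + 1L, frames)
    if (is.na(j)) next
    a <- by_frame[[i]]; b <- by_frame[[j]]
    d <- cross_dist(cbind(table$x[a], table$y[a]),
                    cbind(table$x[b], table$y[b]))
    out[[i]] <- apply(d, 1, min)
  }
  d <- unlist(out, use.names = FALSE)
  if (is.null(d) || length(d) == 0L) {
    stop("need at least two consecutive non-empty frames", call. = FALSE)
  }
  d
}

# Same-molecule re-detection kernel of the NeNA model: the distance
# between two independent 2-D Gaussian position estimates of one emitter
# follows p(d) = d/(2 sigma^2) exp(-d^2 / (4 sigma^2)), a Rayleigh
# density with scale sigma*sqrt(2) and mode at sigma*sqrt(2).
nena_kernel <- function(d, sigma) {
  d / (2 * sigma^2) * exp(-d^2 / (4 * sigma^2))
}

#' Sample from the NeNA same-molecule kernel
#'
#' Draws distances from the pure re-detection kernel for a given average
#' localization precision — the distribution that
#' [fit_nena()] inverts. Useful for calibration and recovery tests.
#'
#' @param n Number of distances.
#' @param sigma Average localization precision, nm.
#' @param seed Optional RNG seed.
#' @return Numeric vector of distances, nm.
#' @export
sample_nena_kernel <- function(n, sigma, seed = NULL) {
  with_seed(seed, sigma * sqrt(2) * sqrt(-2 * log(stats::runif(n))))
}

#' Estimate average localization precision by NeNA
#'
#' Histogram least-squares fit of the adjacent-frame nearest-neighbour
#' distance distribution to the NeNA model: the same-molecule
#' re-detection kernel
#' \deqn{p(d) = A \frac{d}{2\sigma^2} e^{-d^2/(4\sigma^2)}}
#' whose \eqn{\sigma} is the average localization precision, plus optional
#' correction terms absorbing nearby-molecule and uniform background
#' contributions: a Gaussian bump \eqn{B\,\mathcal N(d; d_c, \omega)} and
#' a linear term \eqn{C d}.
#'
#' @param distances Distances from [adjacent_frame_nn_distances()], nm.
#' @param fit_range_max Upper end of the fitted range, nm (default 150;
#'   use ~300 for expanded samples, whose precision is about twice
#'   worse). Distances beyond it are ignored. Bin width is
#'   `fit_range_max / n_bins`.
#' @param n_bins Number of histogram bins (default 100).
#' @param correction Include the background correction terms? Disable for
#'   clean (e.g. simulated pure-kernel) data.
#' @param min_distances Minimum number of usable distances (default 500).
#' @return An object of class `nena_fit` with elements `sigma` (nm),
#'   `amplitudes` (A, B, C), `center`, `omega`, `n_distances`, `rss`
#'   (residual sum of squares of the density fit) and the fitted
#'   histogram (`bin_mid`, `density`, `fitted`).
#' @export
fit_nena <- function(distances, fit_range_max = 150, n_bins = 100L,
                     correction = TRUE, min_distances = 500L) {
  d <- distances[is.finite(distances) & distances >= 0 &
                   distances <= fit_range_max]
  if (length(d) < min_distances) {
    stop(sprintf(
      "only %d usable distances (< %d); too few for a stable NeNA fit",
      length(d), min_distances), call. = FALSE)
  }
  breaks <- seq(0, fit_range_max, length.out = n_bins + 1L)
  bw <- breaks[2] - breaks[1]
  counts <- tabulate(pmin(pmax(floor(d / bw), 0) + 1L, n_bins),
                     nbins = n_bins)
  mid <- breaks[-1L] - bw / 2
  dens <- counts / (length(d) * bw)
  sigma0 <- max(mid[which.max(counts)] / sqrt(2), bw)
  model <- if (correction) {
    function(p) p["A"] * nena_kernel(mid, p["sigma"]) +
      p["B"] * stats::dnorm(mid, p["dc"], p["omega"]) + p["C"] * mid
  } else {
    function(p) p["A"] * nena_kernel(mid, p["sigma"])
  }
  if (correction) {
    start <- c(A = 0.9, sigma = sigma0, B = 0.05, dc = fit_range_max / 2,
               omega = fit_range_max / 4, C = 1e-8)
    lower <- c(A = 0, sigma = bw / 10, B = 0, dc = 0, omega = bw, C = 0)
    upper <- c(A = Inf, sigma = fit_range_max, B = Inf,
               dc = 2 * fit_range_max, omega = 2 * fit_range_max, C = Inf)
  } else {
    start <- c(A = 1, sigma = sigma0)
    lower <- c(A = 0, sigma = bw / 10)
    upper <- c(A = Inf, sigma = fit_range_max)
  }
  fit <- try(minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) dens - model(p),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error") || fit$info %in% c(0L, 5L, 9L)) {
    info <- if (inherits(fit, "try-error")) as.character(fit) else fit$message
    stop(sprintf("NeNA fit did not converge (n = %d, sigma0 = %.3g nm): %s",
                 length(d), sigma0, info), call. = FALSE)
  }
  co <- fit$par
  structure(list(
    sigma = unname(co["sigma"]),
    amplitudes = c(A = unname(co["A"]),
                   B = if (correction) unname(co["B"]) else 0,
                   C = if (correction) unname(co["C"]) else 0),
    center = if (correction) unname(co["dc"]) else NA_real_,
    omega = if (correction) unname(co["omega"]) else NA_real_,
    n_distances = length(d),
    rss = sum(fit$fvec^2),
    bin_mid = mid, density = dens, fitted = model(co)),
    class = "nena_fit")
}

#' @export
print.nena_fit <- function(x, ...) {
  cat(sprintf("NeNA localization precision: sigma = %.2f nm (n = %d distances)\n",
              x$sigma, x$n_distances))
  invisible(x)
}

#' One-call NeNA precision estimate from a localization table
#'
#' Convenience wrapper chaining [adjacent_frame_nn_distances()] and
#' [fit_nena()].
#'
#' @param table A localization table.
#' @inheritParams fit_nena
#' @return A `nena_fit` object.
#' @export
nena_precision <- function(table, fit_range_max = 150, correction = TRUE,
                           min_distances = 500L) {
  fit_nena(adjacent_frame_nn_distances(table),
           fit_range_max = fit_range_max, correction = correction,
           min_distances = min_distances)
}
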