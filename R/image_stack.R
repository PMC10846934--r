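#' Construct an image stack
#'
#' A thin container for wide-field / rendered image data: a 3-D array of
#' non-negative intensities indexed as (frame, row, col), together with
#' the physical pixel size.
#'
#' @param pixels 3-D numeric array (frame, row, col), or a matrix for a
#'   single frame.
#' @param pixel_size nm per pixel; the camera used throughout the study
#'   had 129 nm pixels, rendered images typically use 10 nm.
#' @param exposure ms per frame (metadata only).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(pixels, pixel_size = 129, exposure = NA_real_) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1L, nrow(pixels), ncol(pixels)))
  }
  if (length(dim(pixels)) != 3L) {
    stop("pixels must be a (frame, row, col) array or a matrix",
         call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("pixel_size must be a single positive number", call. = FALSE)
  }
  if (any(pixels < 0, na.rm = TRUE)) {
    stop("pixel intensities must be non-negative", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 exposure = exposure),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px, %.4g nm/px\n",
              d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

# Extract frame i as a matrix.
stack_frame <- function(stack, i = 1L) {
  stack$pixels[i, , , drop = TRUE]
}

#' Read a multi-page TIFF file as an image stack
#'
#' Integer rasters (e.g. uint16 camera data) round-trip losslessly through
#' [write_image_stack()] and this reader.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size nm per pixel to attach to the stack (TIFF files do
#'   not reliably carry physical calibration).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size = 129) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    stop(sprintf("TIFF pages have non-uniform shapes: %s",
                 paste(unique(shapes), collapse = ", ")), call. = FALSE)
  }
  d <- dim(pages[[1]])
  px <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) px[i, , ] <- pages[[i]]
  image_stack(px, pixel_size = pixel_size)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Intensities must fit the uint16 range 0..65535; they are rounded to
#' integers on write.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  px <- stack$pixels
  if (any(px > 65535)) {
    stop("intensities exceed the uint16 range; rescale before writing",
         call. = FALSE)
  }
  pages <- lapply(seq_len(dim(px)[1]), function(i) {
    round(px[i, , , drop = TRUE]) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
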