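#' Multi-channel image stack with physical calibration
#'
#' The pipeline's raw input: named 2D channels (matrices of non-negative
#' camera counts) sharing one geometry, plus the pixel size in micrometres.
#' Pixel `(row, col)` (1-based in R) maps to physical coordinates
#' `x = (col - 1) * pixel_size_um`, `y = (row - 1) * pixel_size_um` at the
#' pixel centre; this convention is used throughout the package.
#'
#' @param channels named list of numeric matrices; names from
#'   `c("axis", "foci", "chromatin")`.
#' @param pixel_size_um positive pixel size, micrometres per pixel.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size_um) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    stop("channels must be a named list of matrices")
  }
  if (!all(names(channels) %in% c("axis", "foci", "chromatin"))) {
    stop("unknown channel name(s): ",
         paste(setdiff(names(channels), c("axis", "foci", "chromatin")),
               collapse = ", "))
  }
  if (!(is.numeric(pixel_size_um) && length(pixel_size_um) == 1L &&
        pixel_size_um > 0)) {
    stop("pixel_size_um must be a positive scalar")
  }
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) {
    stop("all channels must share identical dimensions")
  }
  channels <- lapply(channels, function(ch) {
    ch <- as.matrix(ch)
    if (any(ch < 0)) stop("channel intensities must be non-negative")
    ch
  })
  structure(list(
    channels = channels,
    pixel_size_um = pixel_size_um,
    height_px = nrow(channels[[1L]]),
    width_px = ncol(channels[[1L]])
  ), class = "image_stack")
}

#' Extract one channel from an image stack
#'
#' @param stack an [image_stack()].
#' @param channel channel name.
#' @return The channel matrix.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (!channel %in% names(stack$channels)) {
    stop("unknown channel '", channel, "'; available: ",
         paste(names(stack$channels), collapse = ", "))
  }
  stack$channels[[channel]]
}

#' @export
print.image_stack <- function(x, ...) {
  cat("image_stack:", x$height_px, "x", x$width_px, "px @",
      x$pixel_size_um, "um/px; channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}
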