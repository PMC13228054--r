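#' Colony image container
#'
#' A thin wrapper around a numeric pixel matrix (grayscale) or an
#' `height x width x 3` array (RGB), with a nominal bit depth. Intensities
#' are stored in native units (`0 .. 2^bit_depth - 1`), not rescaled.
#'
#' @param pixels Numeric matrix (grayscale) or 3-slice array (RGB).
#' @param bit_depth Nominal bit depth, 8 or 16.
#' @return An object of class `"colony_image"`.
#' @export
colony_image <- function(pixels, bit_depth = 8L) {
  stopifnot(is.numeric(pixels), bit_depth %in% c(8L, 16L))
  if (!(is.matrix(pixels) || (length(dim(pixels)) == 3 && dim(pixels)[3] == 3)))
    stop("pixels must be a matrix or an RGB array with 3 slices")
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1))
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  structure(list(pixels = pixels,
                 width = ncol(pixels), height = nrow(pixels),
                 bit_depth = as.integer(bit_depth)),
            class = "colony_image")
}

is_rgb <- function(image) length(dim(image$pixels)) == 3

#' @export
print.colony_image <- function(x, ...) {
  cat(sprintf("Colony image: %d x %d px, %s, %d-bit\n", x$width, x$height,
              if (is_rgb(x)) "RGB" else "grayscale", x$bit_depth))
  invisible(x)
}

#' Read a colony image from PNG or TIFF
#'
#' Uses the png/tiff readers and rescales their `[0, 1]` output back to
#' native intensity units. Alpha channels are dropped.
#'
#' @param path File path; format chosen by extension (.png, .tif, .tiff).
#' @param bit_depth Nominal bit depth of the stored image (default 8).
#' @return A [colony_image()].
#' @export
read_colony_image <- function(path, bit_depth = 8L) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(raw)) == 3) {
    if (dim(raw)[3] == 4) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(raw)[3] == 1) raw <- raw[, , 1]
  }
  colony_image(round(raw * (2^bit_depth - 1)), bit_depth = bit_depth)
}

#' Write a colony image as PNG or TIFF
#'
#' @param image A [colony_image()].
#' @param path Destination path (.png, .tif or .tiff).
#' @return `path`, invisibly.
#' @export
write_colony_image <- function(image, path) {
  stopifnot(inherits(image, "colony_image"))
  scaled <- image$pixels / (2^image$bit_depth - 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(scaled, path),
         tif = ,
         tiff = tiff::writeTIFF(scaled, path,
                                bits.per.sample = image$bit_depth),
         stop("unsupported image format: ", ext))
  invisible(path)
}

#' Extract a color channel
#'
#' Projects an RGB image to a single channel. The analysis convention for
#' macrocolony photographs is the green channel; grayscale images pass
#' through unchanged when `channel = "gray"`.
#'
#' @param image A [colony_image()].
#' @param channel One of `"red"`, `"green"`, `"blue"`, `"gray"`.
#' @return A single-channel [colony_image()] of identical dimensions.
#' @export
extract_channel <- function(image,
                            channel = c("green", "red", "blue", "gray")) {
  stopifnot(inherits(image, "colony_image"))
  channel <- match.arg(channel)
  if (!is_rgb(image)) {
    if (channel != "gray")
      stop("image is grayscale; channel '", channel, "' is not present")
    return(image)
  }
  if (channel == "gray")
    stop("image is RGB; select red, green or blue")
  idx <- match(channel, c("red", "green", "blue"))
  colony_image(image$pixels[, , idx], bit_depth = image$bit_depth)
}

#' Subtract the image background and mask the colony
#'
#' Estimates the background level of a single-channel image, masks pixels
#' above it, and subtracts the level from masked pixels (floored at zero).
#' Two strategies:
#' \describe{
#'   \item{`"corner"`}{background level = median of the four `k x k` corner
#'     patches; mask threshold = level + 3 * MAD of those patches. Robust and
#'     parameter-light; the default.}
#'   \item{`"fixed"`}{a user-supplied `threshold`; the background level
#'     subtracted equals the threshold.}
#' }
#'
#' @param image Single-channel [colony_image()].
#' @param strategy `"corner"` or `"fixed"`.
#' @param threshold Intensity threshold for `strategy = "fixed"`.
#' @param k Corner patch side for `strategy = "corner"` (default 16).
#' @return A list of class `"background_result"`: `image` (background-
#'   subtracted [colony_image()]), `mask` (logical matrix), `level`,
#'   `threshold`.
#' @export
subtract_background <- function(image, strategy = c("corner", "fixed"),
                                threshold = NULL, k = 16L) {
  stopifnot(inherits(image, "colony_image"))
  if (is_rgb(image)) stop("background subtraction requires a single channel")
  strategy <- match.arg(strategy)
  px <- image$pixels
  if (strategy == "fixed") {
    if (is.null(threshold)) stop("fixed strategy requires a threshold")
    level <- threshold
  } else {
    k <- min(as.integer(k), nrow(px), ncol(px))
    corners <- c(px[1:k, 1:k], px[1:k, ncol(px) - k + 1:k],
                 px[nrow(px) - k + 1:k, 1:k],
                 px[nrow(px) - k + 1:k, ncol(px) - k + 1:k])
    level <- median(corners)
    threshold <- level + 3 * mad(corners, center = level)
  }
  mask <- px > threshold
  if (!any(mask)) stop("no colony detected: no pixel above background")
  out <- px
  out[mask] <- pmax(out[mask] - level, 0)
  out[!mask] <- 0
  list_out <- list(image = colony_image(out, bit_depth = image$bit_depth),
                   mask = mask, level = level, threshold = threshold)
  class(list_out) <- "background_result"
  list_out
}

#' @export
print.background_result <- function(x, ...) {
  cat(sprintf(
    "Background subtraction: level %.3g, threshold %.3g, %d masked px (%.1f%%)\n",
    x$level, x$threshold, sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Export masked pixels as a coordinate/intensity table
#'
#' One row per masked pixel in row-major order (row by row, left to right),
#' with 0-based coordinates: `x` is the column, `y` the row, origin at the
#' top-left. This is the input domain of [pair_correlation_bruteforce()].
#'
#' @param image Single-channel [colony_image()].
#' @param mask Logical matrix of the same dimensions.
#' @return A data frame with columns `x`, `y`, `intensity`.
#' @export
export_pixels <- function(image, mask) {
  stopifnot(inherits(image, "colony_image"))
  if (is_rgb(image)) stop("export requires a single channel")
  stopifnot(is.logical(mask), all(dim(mask) == dim(image$pixels)))
  if (!any(mask)) stop("empty mask: nothing to export")
  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])  # row-major
  idx <- idx[ord, , drop = FALSE]
  data.frame(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L,
             intensity = image$pixels[mask][ord])
}

#' Re-rasterize a pixel table to an image
#'
#' Inverse of [export_pixels()]: places each `(x, y, intensity)` entry back
#' on a `height x width` canvas of zeros.
#'
#' @param pixels Data frame with columns `x`, `y`, `intensity` (0-based).
#' @param width,height Canvas dimensions in pixels.
#' @param bit_depth Bit depth of the result.
#' @return A [colony_image()].
#' @export
pixels_to_image <- function(pixels, width, height, bit_depth = 8L) {
  .check_pixel_table(pixels)
  stopifnot(all(pixels$x < width), all(pixels$y < height))
  px <- matrix(0, nrow = height, ncol = width)
  px[cbind(pixels$y + 1L, pixels$x + 1L)] <- pixels$intensity
  colony_image(px, bit_depth = bit_depth)
}

.check_pixel_table <- function(pixels) {
  stopifnot(is.data.frame(pixels),
            all(c("x", "y", "intensity") %in% names(pixels)))
  if (nrow(pixels) == 0) stop("empty pixel table")
  if (anyDuplicated(pixels[c("x", "y")]) > 0)
    stop("pixel coordinates must be unique")
  if (any(pixels$intensity < 0)) stop("intensities must be non-negative")
  invisible(pixels)
}

#' Write a pixel table to CSV
#'
#' @param pixels Data frame from [export_pixels()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_pixel_table <- function(pixels, path) {
  .check_pixel_table(pixels)
  write.csv(pixels, path, row.names = FALSE)
  invisible(path)
}
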