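#' Treat pixel intensity as surface height
#'
#' Builds a height field over the colony mask under the working assumption
#' that pixel brightness correlates with how much the biofilm surface
#' protrudes: `z = calibration * intensity`. The calibration scalar (height
#' units per intensity unit, default 1) is supplied by the user; roughness
#' amplitudes scale linearly with it while the dimensionless metrics
#' (skewness, kurtosis, surface-area ratio) use the raw geometry.
#'
#' @param image Single-channel [colony_image()].
#' @param mask Logical matrix marking colony pixels.
#' @param calibration Height units per intensity unit, `> 0`.
#' @return An object of class `"height_field"`: list with `z` (matrix, `NA`
#'   off-mask), `mask`, `calibration`.
#' @export
height_field <- function(image, mask, calibration = 1) {
  stopifnot(inherits(image, "colony_image"))
  if (is_rgb(image)) stop("height field requires a single channel")
  stopifnot(is.logical(mask), all(dim(mask) == dim(image$pixels)),
            calibration > 0)
  if (!any(mask)) stop("empty mask")
  z <- image$pixels * calibration
  z[!mask] <- NA_real_
  structure(list(z = z, mask = mask, calibration = calibration),
            class = "height_field")
}

#' Roughness metrics of a height field
#'
#' Standard areal surface-texture statistics of the masked heights `z` with
#' mean `zbar`:
#' \describe{
#'   \item{Ra}{`mean(|z - zbar|)` — arithmetic mean deviation.}
#'   \item{Rq}{`sqrt(mean((z - zbar)^2))` — RMS deviation.}
#'   \item{Rsk}{`mean((z - zbar)^3) / Rq^3` — skewness (dimensionless).}
#'   \item{Rku}{`mean((z - zbar)^4) / Rq^4` — kurtosis (dimensionless).}
#'   \item{Rt}{`max(z) - min(z)` — peak-to-valley height.}
#' }
#' On a perfectly flat field (`Rq = 0`) the dimensionless moments are
#' undefined and reported as `NA` with `defined = FALSE` rather than
#' propagating `NaN`.
#'
#' @param field A [height_field()] with at least 2 masked pixels.
#' @return An object of class `"surface_metrics"` with fields `Ra`, `Rq`,
#'   `Rsk`, `Rku`, `Rt`, `defined`, `n`.
#' @examples
#' img <- colony_image(matrix(c(0, 0, 0, 4), 2, 2))
#' m <- roughness_metrics(height_field(img, matrix(TRUE, 2, 2)))
#' m$Rsk  # 2/sqrt(3)
#' @export
roughness_metrics <- function(field) {
  stopifnot(inherits(field, "height_field"))
  z <- field$z[field$mask]
  if (length(z) < 2) stop("need at least 2 masked pixels")
  zc <- z - mean(z)
  Rq <- sqrt(mean(zc^2))
  defined <- Rq > 0
  structure(list(Ra = mean(abs(zc)), Rq = Rq,
                 Rsk = if (defined) mean(zc^3) / Rq^3 else NA_real_,
                 Rku = if (defined) mean(zc^4) / Rq^4 else NA_real_,
                 Rt = max(z) - min(z),
                 defined = defined, n = length(z)),
            class = "surface_metrics")
}

#' Surface-area ratio of a height field
#'
#' The developed area of the lifted surface divided by its projected area.
#' Each fully-masked 2x2 pixel block ("unit cell", 1 px^2 projected) is split
#' along a fixed diagonal into two triangles with vertices at the pixel
#' centres lifted to their heights; SA is the summed triangle area divided by
#' the number of complete unit cells. A flat field gives exactly 1; any
#' relief gives `SA > 1`, and SA is invariant under a constant height offset.
#'
#' @param field A [height_field()] whose mask contains at least one complete
#'   2x2 block.
#' @return The surface-area ratio (scalar `>= 1`).
#' @export
surface_area_ratio <- function(field) {
  stopifnot(inherits(field, "height_field"))
  z <- field$z
  m <- field$mask
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2) stop("no complete unit cell in mask")
  cell <- m[-nr, -nc] & m[-1, -nc] & m[-nr, -1] & m[-1, -1]
  if (!any(cell)) stop("no complete unit cell in mask")
  zA <- z[-nr, -nc][cell]  # (x,   y)
  zB <- z[-nr, -1][cell]   # (x+1, y)
  zC <- z[-1, -nc][cell]   # (x,   y+1)
  zD <- z[-1, -1][cell]    # (x+1, y+1)
  # triangles ABD and ACD, split along the A-D diagonal; pixel pitch = 1
  tri <- function(u1, v1, w1, u2, v2, w2) {
    # area of triangle with edge vectors (1,0,u...) expressed generically
    cx <- v1 * w2 - w1 * v2
    cy <- w1 * u2 - u1 * w2
    cz <- u1 * v2 - v1 * u2
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  # edges from A: AB = (1,0,zB-zA), AD = (1,1,zD-zA), AC = (0,1,zC-zA)
  a1 <- tri(1, 0, zB - zA, 1, 1, zD - zA)
  a2 <- tri(0, 1, zC - zA, 1, 1, zD - zA)
  sum(a1 + a2) / sum(cell)
}

#' All surface metrics of a colony image
#'
#' Convenience wrapper: builds the height field and returns the five
#' roughness statistics together with the surface-area ratio.
#'
#' @inheritParams height_field
#' @return A `"surface_metrics"` object with an additional `SA` field.
#' @export
surface_metrics <- function(image, mask, calibration = 1) {
  field <- height_field(image, mask, calibration)
  out <- roughness_metrics(field)
  out$SA <- surface_area_ratio(field)
  out
}

#' @export
print.surface_metrics <- function(x, ...) {
  cat("Surface metrics over", x$n, "pixels:\n")
  cat(sprintf("  Ra = %.4g  Rq = %.4g  Rt = %.4g\n", x$Ra, x$Rq, x$Rt))
  if (x$defined)
    cat(sprintf("  Rsk = %.4g  Rku = %.4g\n", x$Rsk, x$Rku))
  else
    cat("  Rsk, Rku undefined (flat field)\n")
  if (!is.null(x$SA)) cat(sprintf("  SA = %.4g\n", x$SA))
  invisible(x)
}
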