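#' Normalized radial pair-correlation of a masked image
#'
#' @description
#' Both [pair_correlation_bruteforce()] and [pair_correlation_fft()] compute
#' the normalized pairwise correlation function
#' \deqn{\gamma(r) = \langle I(x) I(y) \rangle / \langle I^2 \rangle,}
#' the average product of the intensities of two pixels separated by
#' Euclidean distance `r`, divided by the average squared intensity over all
#' pixels. Pairs are radially binned with width `bin_width`; bin 0 contains
#' exactly the self-pairs, so `gamma(0) = 1` by construction in the
#' uncentered variant. With `centered = TRUE`, intensities are replaced by
#' their deviation from the masked mean and the normalizer by the intensity
#' variance before the same computation; the centered variant is the one that
#' decays to zero for unstructured fields and is required by
#' [correlation_summary()].
#'
#' The brute-force path enumerates every unordered pixel pair (the exact
#' reference definition); above `max_pixels_exact` pixels it switches to
#' seeded uniform pair subsampling unless `exact = TRUE`. The FFT path
#' obtains the identical quantity from the zero-padded autocorrelation of
#' the masked intensity field (numerator) and of the binary mask (pair
#' counts), and is exact and fast at full-image scale.
#'
#' Binning: a cross pair at distance `d` falls in bin
#' `max(1, floor(d / bin_width))`; self-pairs occupy bin 0 alone. Reported
#' `r` values are the left bin edges `k * bin_width`.
#'
#' @param pixels Data frame with columns `x`, `y`, `intensity`
#'   (see [export_pixels()]).
#' @param bin_width Radial bin width, pixels (default 1).
#' @param max_r Maximum distance considered; default half the diameter of
#'   the pixel cloud's bounding box.
#' @param centered Logical; mean-centre intensities first (default `FALSE`,
#'   the literal definition above).
#' @param max_pixels_exact Pixel count above which the brute-force path
#'   subsamples pairs (default 20000).
#' @param n_sample_pairs Number of sampled cross pairs when subsampling.
#' @param exact Force exhaustive enumeration regardless of size.
#' @param seed Seed for pair subsampling only.
#' @return An object of class `"pair_correlation"`: list with `r` (left bin
#'   edges), `gamma`, `pairs` (pair counts per bin), `bin_width`,
#'   `mean_square` (the normalizer), `centered`, `method`.
#' @examples
#' px <- data.frame(x = 0:2, y = 0, intensity = 1:3)
#' g <- pair_correlation_bruteforce(px)
#' g$gamma  # 1, 6/7, 9/14
#' @export
pair_correlation_bruteforce <- function(pixels, bin_width = 1, max_r = NULL,
                                        centered = FALSE,
                                        max_pixels_exact = 20000L,
                                        n_sample_pairs = 5e6,
                                        exact = FALSE, seed = 1L) {
  .check_pixel_table(pixels)
  stopifnot(bin_width > 0)
  I <- pixels$intensity
  n <- length(I)
  if (centered) I <- I - mean(I)
  norm <- sum(I^2) / n  # same expression as the bin-0 mean: gamma(0) = 1 exactly
  if (norm == 0) stop("degenerate field: zero ", if (centered) "variance"
                      else "mean square intensity")
  if (is.null(max_r)) max_r <- .default_max_r(pixels)
  n_bins <- max(1L, floor(max_r / bin_width)) + 1L
  num <- cnt <- numeric(n_bins)
  # bin 0: self-pairs only
  num[1L] <- sum(I^2)
  cnt[1L] <- n
  subsample <- n > max_pixels_exact && !exact
  if (!subsample && n >= 2) {
    # exhaustive unordered pairs, blocked to bound memory
    block <- 2000L
    starts <- seq(1L, n - 1L, by = block)
    for (s in starts) {
      rows <- s:min(s + block - 1L, n - 1L)
      for (i in rows) {
        j <- (i + 1L):n
        d <- sqrt((pixels$x[i] - pixels$x[j])^2 +
                  (pixels$y[i] - pixels$y[j])^2)
        keep <- d <= max_r
        if (!any(keep)) next
        b <- pmax(1L, floor(d[keep] / bin_width)) + 1L
        p <- I[i] * I[j][keep]
        num <- num + .bin_sum(p, b, n_bins)
        cnt <- cnt + .bin_sum(rep(1, length(b)), b, n_bins)
      }
    }
  } else if (subsample) {
    with_seed(seed, {
      i <- sample.int(n, n_sample_pairs, replace = TRUE)
      j <- sample.int(n, n_sample_pairs, replace = TRUE)
      keep <- i != j
      i <- i[keep]; j <- j[keep]
      d <- sqrt((pixels$x[i] - pixels$x[j])^2 +
                (pixels$y[i] - pixels$y[j])^2)
      keep <- d <= max_r
      b <- pmax(1L, floor(d[keep] / bin_width)) + 1L
      num[-1L] <- num[-1L] + .bin_sum(I[i][keep] * I[j][keep], b, n_bins)[-1L]
      cnt[-1L] <- cnt[-1L] + .bin_sum(rep(1, length(b)), b, n_bins)[-1L]
    })
  }
  .pair_correlation_result(num, cnt, n_bins, bin_width, norm, centered,
                           method = if (subsample) "bruteforce-sampled"
                                    else "bruteforce")
}

.bin_sum <- function(values, bins, n_bins) {
  out <- numeric(n_bins)
  agg <- rowsum(values, bins)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

.default_max_r <- function(pixels) {
  dx <- diff(range(pixels$x)); dy <- diff(range(pixels$y))
  max(1, sqrt(dx^2 + dy^2) / 2)
}

.pair_correlation_result <- function(num, cnt, n_bins, bin_width, norm,
                                     centered, method) {
  gamma <- ifelse(cnt > 0, num / cnt / norm, NA_real_)
  structure(list(r = (seq_len(n_bins) - 1L) * bin_width,
                 gamma = gamma, pairs = cnt, bin_width = bin_width,
                 mean_square = norm, centered = centered, method = method),
            class = "pair_correlation")
}

#' @rdname pair_correlation_bruteforce
#' @param image Single-channel [colony_image()] (background-subtracted).
#' @param mask Logical matrix marking colony pixels.
#' @export
pair_correlation_fft <- function(image, mask, bin_width = 1, max_r = NULL,
                                 centered = FALSE) {
  stopifnot(inherits(image, "colony_image"))
  if (is_rgb(image)) stop("pair correlation requires a single channel")
  stopifnot(is.logical(mask), all(dim(mask) == dim(image$pixels)))
  if (!any(mask)) stop("empty mask")
  stopifnot(bin_width > 0)
  Z <- image$pixels
  Z[!mask] <- 0
  if (centered) Z[mask] <- Z[mask] - mean(Z[mask])
  norm <- sum(Z[mask]^2) / sum(mask)
  if (norm == 0) stop("degenerate field: zero ", if (centered) "variance"
                      else "mean square intensity")
  if (is.null(max_r)) {
    idx <- which(mask, arr.ind = TRUE)
    max_r <- .default_max_r(data.frame(x = idx[, 2L], y = idx[, 1L]))
  }
  nr <- nrow(Z); nc <- ncol(Z)
  # zero-padded 2D autocorrelation of the intensity field and of the mask;
  # cell (dy, dx) holds the sum over ordered pairs at that displacement
  pr <- 2L * nr; pc <- 2L * nc
  pad <- function(M) { P <- matrix(0, pr, pc); P[1:nr, 1:nc] <- M; P }
  acf2 <- function(M) {
    F <- fft(pad(M))
    Re(fft(F * Conj(F), inverse = TRUE)) / (pr * pc)
  }
  A <- acf2(Z)
  C <- round(acf2(mask * 1))
  # displacement grid of the wrapped autocorrelation
  dyv <- c(0:(nr - 1), rep(NA, 1), -( (nr - 1):1 ))
  dxv <- c(0:(nc - 1), rep(NA, 1), -( (nc - 1):1 ))
  dy <- matrix(rep(dyv, times = pc), pr, pc)
  dx <- matrix(rep(dxv, each = pr), pr, pc)
  d <- sqrt(dx^2 + dy^2)
  valid <- !is.na(d) & C > 0 & d <= max_r
  n_bins <- max(1L, floor(max_r / bin_width)) + 1L
  b <- pmax(1L, floor(d[valid] / bin_width)) + 1L
  b[d[valid] == 0] <- 1L  # the (0,0) displacement = self-pairs
  num <- .bin_sum(A[valid], b, n_bins)
  cnt <- .bin_sum(C[valid], b, n_bins)
  # the autocorrelation counts ordered pairs; report unordered (self-pairs,
  # bin 0, occur once) so counts match the brute-force enumeration
  num[-1L] <- num[-1L] / 2
  cnt[-1L] <- cnt[-1L] / 2
  # bin 0 analytically: self-pairs only, free of FFT roundoff
  num[1L] <- sum(Z[mask]^2)
  cnt[1L] <- sum(mask)
  .pair_correlation_result(num, cnt, n_bins, bin_width, norm, centered,
                           method = "fft")
}

#' @export
print.pair_correlation <- function(x, ...) {
  cat(sprintf(
    "Pair correlation (%s, %s): %d bins of width %g px, gamma(0) = %.6g\n",
    x$method, if (x$centered) "centered" else "uncentered",
    length(x$r), x$bin_width, x$gamma[1L]))
  invisible(x)
}

#' @export
plot.pair_correlation <- function(x, ...) {
  graphics::plot(x$r, x$gamma, type = "l", xlab = "r (px)",
                 ylab = expression(gamma(r)), ...)
  graphics::abline(h = if (x$centered) 0 else NA, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.pair_correlation <- function(x, ...) {
  data.frame(r = x$r, gamma = x$gamma, pairs = x$pairs)
}

#' Decay and oscillation summary of a centered pair-correlation function
#'
#' Summarizes a mean-centred correlation curve by its decay length and the
#' period of its first oscillation, the quantitative counterparts of the
#' qualitative readings of structured vs unstructured colony images: slowly
#' decaying curves indicate large objects, oscillations indicate repeating
#' spatial motifs (wrinkles), and a fast structureless decay indicates
#' random texture.
#'
#' The correlation length is the smallest binned distance with
#' `gamma < 1/e`. The oscillation period is the distance of the first local
#' maximum that follows the first local minimum of the (lightly smoothed)
#' curve; it is `NA` if no such maximum reaches `amplitude_threshold`.
#'
#' @param corr A `"pair_correlation"` computed with `centered = TRUE`.
#' @param amplitude_threshold Minimum `gamma` at the rebound maximum for an
#'   oscillation to be reported (default 0.05).
#' @param smooth Odd window length of the running-mean smoother applied
#'   before extremum detection (default 3; 1 = none).
#' @return A list of class `"correlation_summary"`: `correlation_length`,
#'   `oscillation_period` (`NA` if none), `oscillation_amplitude`.
#' @export
correlation_summary <- function(corr, amplitude_threshold = 0.05,
                                smooth = 3L) {
  stopifnot(inherits(corr, "pair_correlation"))
  if (!corr$centered)
    stop("correlation_summary requires a centered correlation function")
  ok <- !is.na(corr$gamma)
  g <- corr$gamma[ok]; r <- corr$r[ok]
  if (length(g) < 5) stop("need at least 5 populated bins")
  if (smooth > 1) {
    k <- as.integer(smooth)
    if (k %% 2 == 0) k <- k + 1L
    gs <- stats::filter(g, rep(1 / k, k), sides = 2)
    gs[is.na(gs)] <- g[is.na(gs)]
    g <- as.numeric(gs)
  }
  below <- which(g < exp(-1))
  corr_len <- if (length(below)) r[below[1L]] else r[length(r)]
  dgn <- diff(g)
  period <- amp <- NA_real_
  # first local minimum, then the first local maximum after it
  mins <- which(dgn[-length(dgn)] < 0 & dgn[-1L] >= 0) + 1L
  if (length(mins)) {
    i0 <- mins[1L]
    dg2 <- dgn[i0:length(dgn)]
    maxs <- which(dg2[-length(dg2)] > 0 & dg2[-1L] <= 0) + i0
    if (length(maxs)) {
      i1 <- maxs[1L]
      if (g[i1] >= amplitude_threshold) {
        period <- r[i1]
        amp <- g[i1]
      }
    }
  }
  structure(list(correlation_length = corr_len,
                 oscillation_period = period,
                 oscillation_amplitude = amp),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat("Correlation length:", x$correlation_length, "px\n")
  if (is.na(x$oscillation_period)) {
    cat("No oscillation detected\n")
  } else {
    cat(sprintf("Oscillation: period %g px, amplitude %.3g\n",
                x$oscillation_period, x$oscillation_amplitude))
  }
  invisible(x)
}
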