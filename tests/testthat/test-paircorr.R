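test_that("collinear three-pixel example matches exhaustive enumeration", {
  px <- data.frame(x = 0:2, y = 0, intensity = 1:3)
  g <- pair_correlation_bruteforce(px, bin_width = 1, max_r = 2)
  # <I^2> = 14/3; gamma(1) = mean(1*2, 2*3)/<I^2> = 6/7;
  # gamma(2) = 1*3 / <I^2> = 9/14
  expect_equal(g$gamma, c(1, 6 / 7, 9 / 14))
  expect_equal(g$pairs, c(3, 2, 1))
})

test_that("gamma(0) = 1 and constant fields give gamma identically 1", {
  for (seed in 1:3) {
    disk <- random_disk(seed = seed)
    tab <- export_pixels(disk, disk_mask(disk))
    g <- pair_correlation_bruteforce(tab, max_r = 10)
    expect_identical(g$gamma[1], 1)
  }
  const <- data.frame(x = rep(0:3, 4), y = rep(0:3, each = 4),
                      intensity = 7)
  g <- pair_correlation_bruteforce(const, max_r = 4)
  expect_equal(g$gamma[g$pairs > 0], rep(1, sum(g$pairs > 0)))

  # all-zero intensities are degenerate
  zero <- data.frame(x = 0:3, y = 0, intensity = 0)
  expect_error(pair_correlation_bruteforce(zero), "degenerate field")
  expect_error(pair_correlation_bruteforce(const, centered = TRUE),
               "degenerate field")
})

test_that("FFT path agrees with brute force to 1e-9 on masked fixtures", {
  for (seed in 1:5) {
    disk <- random_disk(seed = seed, size = 64L, radius = 24)
    mask <- disk_mask(disk)
    tab <- export_pixels(disk, mask)
    for (centered in c(FALSE, TRUE)) {
      bf <- pair_correlation_bruteforce(tab, max_r = 30,
                                        centered = centered)
      ff <- pair_correlation_fft(disk, mask, max_r = 30,
                                 centered = centered)
      expect_lt(max(abs(bf$gamma - ff$gamma), na.rm = TRUE), 1e-9)
      expect_equal(bf$pairs, ff$pairs)
    }
  }
  # full-mask constant image
  cimg <- colony_image(matrix(9, 16, 16))
  ff <- pair_correlation_fft(cimg, matrix(TRUE, 16, 16))
  expect_equal(ff$gamma[ff$pairs > 0], rep(1, sum(ff$pairs > 0)))
  expect_identical(ff$gamma[1], 1)
})

test_that("gamma is invariant to pixel-table row order", {
  disk <- random_disk(seed = 7, size = 32L, radius = 12)
  tab <- export_pixels(disk, disk_mask(disk))
  shuf <- tab[sample(nrow(tab)), ]
  g1 <- pair_correlation_bruteforce(tab, max_r = 12)
  g2 <- pair_correlation_bruteforce(shuf, max_r = 12)
  expect_equal(g1$gamma, g2$gamma)
  expect_equal(g1$pairs, g2$pairs)
})

test_that("uncentered gamma of an uncorrelated field plateaus at mean^2/<I^2>", {
  disk <- random_disk(seed = 8, size = 64L, radius = 24, baseline = 100,
                      noise_sd = 50)
  mask <- disk_mask(disk)
  tab <- export_pixels(disk, mask)
  I <- tab$intensity
  plateau <- mean(I)^2 / mean(I^2)
  g <- pair_correlation_fft(disk, mask, max_r = 20)
  mid <- g$gamma[4:15]
  expect_lt(max(abs(mid - plateau)), 0.05)
  expect_gt(plateau, 0.5)  # distinctly not zero: the centering caveat
})

test_that("mean-centered correlation of i.i.d. noise vanishes beyond r = 0", {
  disk <- random_disk(seed = 9, size = 64L, radius = 24, baseline = 100,
                      noise_sd = 50)
  tab <- export_pixels(disk, disk_mask(disk))
  g <- pair_correlation_bruteforce(tab, max_r = 20, centered = TRUE)
  expect_lt(abs(g$gamma[6]), 0.1)  # r = 5 * bin_width
  s <- correlation_summary(g)
  expect_true(is.na(s$oscillation_period))
  expect_lte(s$correlation_length, 2 * g$bin_width)
})

test_that("oscillation summary recovers the wrinkle wavelength", {
  img <- wrinkled_disk(seed = 10)
  corr <- pair_correlation_fft(img, disk_mask(img), max_r = 70,
                               centered = TRUE)
  s <- correlation_summary(corr)
  expect_false(is.na(s$oscillation_period))
  expect_gte(s$oscillation_period, 18)
  expect_lte(s$oscillation_period, 22)
  expect_gte(s$oscillation_amplitude, 0.05)
})

test_that("summary contract: centered input and enough bins required", {
  img <- wrinkled_disk(seed = 11, size = 120L, radius = 50)
  corr_u <- pair_correlation_fft(img, disk_mask(img), max_r = 40)
  expect_error(correlation_summary(corr_u), "centered")
  px <- data.frame(x = 0:3, y = 0, intensity = c(1, 5, 2, 4))
  tiny <- pair_correlation_bruteforce(px, max_r = 3, centered = TRUE)
  expect_error(correlation_summary(tiny), "at least 5")
})

test_that("pair subsampling engages above the exact-size cap and stays seeded", {
  disk <- random_disk(seed = 12, size = 48L, radius = 20)
  tab <- export_pixels(disk, disk_mask(disk))
  g1 <- pair_correlation_bruteforce(tab, max_r = 15, max_pixels_exact = 100,
                                    n_sample_pairs = 2e5, seed = 5)
  g2 <- pair_correlation_bruteforce(tab, max_r = 15, max_pixels_exact = 100,
                                    n_sample_pairs = 2e5, seed = 5)
  expect_identical(g1$gamma, g2$gamma)
  expect_equal(g1$method, "bruteforce-sampled")
  exact <- pair_correlation_bruteforce(tab, max_r = 15)
  expect_identical(g1$gamma[1], 1)
  expect_lt(max(abs(g1$gamma - exact$gamma), na.rm = TRUE), 0.05)
})
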