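# Small in-code fixtures shared across test files.

# Noisy disk with no spatial structure on a zero background.
random_disk <- function(seed = 1, size = 48L, radius = 18, baseline = 100,
                        noise_sd = 20) {
  sim_random_colony(colony_spec(
    image_size = size, radius = radius, baseline = baseline, amplitude = 0,
    wavelength = 10, noise_sd = noise_sd, background_level = 0, seed = seed))
}

# Wrinkled disk with a known concentric wavelength.
wrinkled_disk <- function(seed = 1, size = 200L, radius = 90,
                          wavelength = 20, amplitude = 60, noise_sd = 5) {
  sim_wrinkled_colony(colony_spec(
    image_size = size, radius = radius, baseline = 120,
    amplitude = amplitude, wavelength = wavelength, noise_sd = noise_sd,
    background_level = 0, seed = seed))
}

disk_mask <- function(image) image$pixels > 0

# Tiny RGB test image with distinct channels.
rgb_image <- function() {
  px <- array(0, c(2, 2, 3))
  px[, , 1] <- 10; px[, , 2] <- 200; px[, , 3] <- 30
  colony_image(px)
}
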