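#' Specification for a synthetic macrocolony image
#'
#' Bundles and validates the geometry, intensity and noise parameters used by
#' [sim_wrinkled_colony()] and [sim_random_colony()]. The synthetic colony is
#' a bright disk on a dark background; the wrinkled variant adds a concentric
#' sinusoidal relief of known wavelength so that downstream estimates
#' (oscillation period of the pair-correlation function, surface roughness)
#' can be checked against ground truth.
#'
#' @param image_size Side of the square image, pixels.
#' @param radius Colony radius, pixels; must satisfy `radius < image_size/2`.
#' @param baseline Mean intensity inside the colony, intensity units.
#' @param amplitude Amplitude of the concentric sinusoid, intensity units.
#' @param wavelength Wavelength of the sinusoid, pixels; must be positive.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param background_level Intensity of the background outside the disk.
#' @param seed Integer seed; identical seeds give bit-identical images.
#' @return An object of class `"colony_spec"` (a validated list).
#' @examples
#' spec <- colony_spec(image_size = 128, radius = 50, wavelength = 20)
#' img <- sim_wrinkled_colony(spec)
#' @export
colony_spec <- function(image_size = 256, radius = 100, baseline = 150,
                        amplitude = 40, wavelength = 20, noise_sd = 5,
                        background_level = 5, seed = 1L) {
  stopifnot(image_size >= 4, radius > 0, wavelength > 0,
            amplitude >= 0, noise_sd >= 0, background_level >= 0,
            baseline >= 0)
  if (radius >= image_size / 2)
    stop("invalid geometry: radius must be < image_size/2")
  structure(list(image_size = as.integer(image_size), radius = radius,
                 baseline = baseline, amplitude = amplitude,
                 wavelength = wavelength, noise_sd = noise_sd,
                 background_level = background_level,
                 seed = as.integer(seed)),
            class = "colony_spec")
}

# Distance of every pixel centre from the image centre.
.radial_distance <- function(n) {
  ctr <- (n - 1) / 2
  dx <- matrix(rep(0:(n - 1), each = n), n, n) - ctr   # column index
  dy <- matrix(rep(0:(n - 1), times = n), n, n) - ctr  # row index
  sqrt(dx^2 + dy^2)
}

#' Simulate a wrinkled macrocolony image
#'
#' Renders a disk of intensity `baseline + amplitude * sin(2*pi*d/wavelength)`
#' (with `d` the distance from the colony centre) plus Gaussian noise, clipped
#' at zero, on a uniform background. The concentric sinusoid emulates the
#' repeating wrinkle motif that makes the pair-correlation function of real
#' structured colonies oscillate.
#'
#' @param spec A [colony_spec()].
#' @return A grayscale [colony_image()].
#' @export
sim_wrinkled_colony <- function(spec) {
  stopifnot(inherits(spec, "colony_spec"))
  n <- spec$image_size
  d <- .radial_distance(n)
  inside <- d <= spec$radius
  px <- matrix(spec$background_level, n, n)
  relief <- spec$baseline +
    spec$amplitude * sin(2 * pi * d[inside] / spec$wavelength)
  px[inside] <- with_seed(spec$seed,
    relief + rnorm(sum(inside), 0, spec$noise_sd))
  px[px < 0] <- 0
  colony_image(px, bit_depth = if (max(px) > 255) 16L else 8L)
}

#' Simulate a structureless (random) colony image
#'
#' Same disk geometry as [sim_wrinkled_colony()] but the interior is i.i.d.
#' Gaussian noise around `baseline` with no spatial structure: the
#' mean-centred pair-correlation of such an image decays to zero essentially
#' immediately, the behaviour expected of unstructured pixels.
#'
#' @inheritParams sim_wrinkled_colony
#' @return A grayscale [colony_image()].
#' @export
sim_random_colony <- function(spec) {
  stopifnot(inherits(spec, "colony_spec"))
  n <- spec$image_size
  d <- .radial_distance(n)
  inside <- d <= spec$radius
  px <- matrix(spec$background_level, n, n)
  px[inside] <- with_seed(spec$seed,
    spec$baseline + rnorm(sum(inside), 0, spec$noise_sd))
  px[px < 0] <- 0
  colony_image(px, bit_depth = if (max(px) > 255) 16L else 8L)
}

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Forward model of the Lea-Coulson distribution: each culture receives
#' `M ~ Poisson(m)` mutation events with `m = rate * Nt`; each event founds a
#' resistant clone whose final size is drawn as `floor(1/U)`, `U ~ U(0,1)`
#' (exactly the `P(J = j) = 1/(j(j+1))` clone-size law, since
#' `P(J >= k) = 1/k`), truncated at `Nt`. The per-culture mutant count is the
#' sum of clone sizes. Mutant fitness, death, and partial plating are not
#' modelled (constant-fitness Lea-Coulson assumptions, full plating).
#'
#' @param rate Per-cell mutation rate (mutations per cell per generation-
#'   equivalent as in a fluctuation assay), `>= 0`.
#' @param Nt Final population size per culture, cells, `>= 1`.
#' @param n_cultures Number of parallel cultures, `>= 1`.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `"fluctuation_experiment"`: a list with
#'   `counts` (integer-valued numeric vector), `Nt`, `n_cultures`.
#' @examples
#' ex <- sim_fluctuation(rate = 5e-10, Nt = 1e9, n_cultures = 84, seed = 1)
#' fit_mutation_rate(ex, ci = FALSE)
#' @export
sim_fluctuation <- function(rate, Nt, n_cultures, seed = NULL) {
  stopifnot(rate >= 0, Nt >= 1, n_cultures >= 1)
  m <- rate * Nt
  counts <- with_seed(seed, {
    mutations <- rpois(n_cultures, m)
    total <- sum(mutations)
    if (total == 0) numeric(n_cultures) else {
      clone <- pmin(floor(1 / runif(total)), Nt)
      cult <- rep.int(seq_len(n_cultures), mutations)
      cnt <- numeric(n_cultures)
      agg <- rowsum(clone, cult)
      cnt[as.integer(rownames(agg))] <- agg[, 1L]
      cnt
    }
  })
  fluctuation_experiment(counts, Nt)
}

#' Construct a fluctuation experiment from observed counts
#'
#' @param counts Non-negative integer mutant counts, one per culture.
#' @param Nt Final population size (per-strain mean), cells.
#' @return An object of class `"fluctuation_experiment"`.
#' @export
fluctuation_experiment <- function(counts, Nt) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) >= 1, all(is.finite(counts)),
            all(counts >= 0), all(counts == floor(counts)), Nt > 0)
  structure(list(counts = counts, Nt = Nt, n_cultures = length(counts)),
            class = "fluctuation_experiment")
}

#' @export
print.fluctuation_experiment <- function(x, ...) {
  cat("Fluctuation experiment:", x$n_cultures, "cultures, Nt =",
      format(x$Nt, scientific = TRUE), "\n")
  cat("  mutant counts: median", median(x$counts),
      " max", max(x$counts),
      " zero fraction", signif(mean(x$counts == 0), 3), "\n")
  invisible(x)
}

#' Simulate a competition-assay quartet
#'
#' Generates the four integrated-density measurements of one competition
#' pair: the two monocultures and the two channels of the coculture.
#' Monoculture densities are proportional to each strain's reporter
#' expression factor; coculture densities are proportional to
#' `true fraction x expression factor`, so monoculture normalization cancels
#' the expression factors exactly in the noiseless case.
#'
#' @param true_fraction_A True fraction of strain A in the coculture, in
#'   `[0, 1]`.
#' @param expression_factor_A,expression_factor_B Reporter brightness factors
#'   (e.g. GFP vs mKate expression strength), `> 0`.
#' @param noise_sd Standard deviation of multiplicative lognormal noise
#'   applied independently to each of the four densities (0 = noiseless).
#' @param seed Optional integer seed.
#' @return An object of class `"competition_quartet"`: list with `co_A`,
#'   `co_B`, `mono_A`, `mono_B`.
#' @export
sim_competition_quartet <- function(true_fraction_A,
                                    expression_factor_A = 1,
                                    expression_factor_B = 1,
                                    noise_sd = 0, seed = NULL) {
  stopifnot(true_fraction_A >= 0, true_fraction_A <= 1,
            expression_factor_A > 0, expression_factor_B > 0, noise_sd >= 0)
  base <- 1e6  # arbitrary total signal scale; cancels in normalization
  q <- c(co_A = base * true_fraction_A * expression_factor_A,
         co_B = base * (1 - true_fraction_A) * expression_factor_B,
         mono_A = base * expression_factor_A,
         mono_B = base * expression_factor_B)
  if (noise_sd > 0)
    q <- with_seed(seed, q * exp(rnorm(4, 0, noise_sd)))
  structure(as.list(q), class = "competition_quartet")
}

#' Simulate outgrowth-screening records
#'
#' Bernoulli draws per screened colony: each colony of a strain develops a
#' peripheral outgrowth with that strain's probability. Outgrowths are
#' assigned a morphotype class from `class_probs`; colonies without an
#' outgrowth carry class `"none"` (the invariant enforced by
#' [tally_outgrowths()]).
#'
#' @param strain_probs Named numeric vector: per-strain outgrowth probability
#'   in `[0, 1]`.
#' @param n_per_strain Colonies screened per strain.
#' @param class_probs Named probability vector over morphotype classes for
#'   outgrowths; defaults to the three classes seen in practice.
#' @param experiment_id Identifier recorded in every row.
#' @param seed Optional integer seed.
#' @return A data frame with columns `strain`, `experiment_id`, `colony_id`,
#'   `outgrowth` (logical), `morphotype_class`.
#' @export
sim_screening_records <- function(strain_probs, n_per_strain,
                                  class_probs = c("mut-swrA" = 0.55,
                                                  "mut-unk" = 0.40,
                                                  "mut-comP" = 0.05),
                                  experiment_id = 1L, seed = NULL) {
  stopifnot(length(strain_probs) >= 1, !is.null(names(strain_probs)),
            all(strain_probs >= 0), all(strain_probs <= 1),
            n_per_strain >= 1, all(class_probs >= 0), sum(class_probs) > 0)
  class_probs <- class_probs / sum(class_probs)
  with_seed(seed, {
    rows <- lapply(names(strain_probs), function(s) {
      out <- runif(n_per_strain) < strain_probs[[s]]
      cls <- rep("none", n_per_strain)
      if (any(out))
        cls[out] <- sample(names(class_probs), sum(out), replace = TRUE,
                           prob = class_probs)
      data.frame(strain = s, experiment_id = experiment_id,
                 colony_id = seq_len(n_per_strain),
                 outgrowth = out, morphotype_class = cls,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
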