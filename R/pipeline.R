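#' Validate a pipeline run configuration
#'
#' Accepts either a YAML file path or a list. Recognized fields (all
#' optional unless a stage needs them): `images` (character vector of image
#' paths), `channel`, `background` (`strategy`, `threshold`, `k`),
#' `bin_width`, `max_r`, `centered`, `calibration`, `counts_csv`,
#' `popsize_csv`, `cap`, `ci_level`, `comparisons`, `seed`, `output_dir`.
#' Referenced paths must exist at validation time.
#'
#' @param config YAML path or list.
#' @return The validated config (list, class `"run_config"`) with defaults
#'   filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(channel = "green", bin_width = 1, max_r = NULL,
                   centered = TRUE, calibration = 1, cap = 1e4,
                   ci_level = 0.95, seed = 1L, output_dir = tempfile("run"),
                   background = list(strategy = "corner", k = 16L,
                                     threshold = NULL))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in names(defaults$background))
    if (is.null(config$background[[nm]]))
      config$background[[nm]] <- defaults$background[[nm]]
  for (p in c(config$images, config$counts_csv, config$popsize_csv))
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  structure(config, class = "run_config")
}

.run_provenance <- function(config) {
  list(seed = config$seed,
       package_version = as.character(packageVersion("macromorph")),
       config = unclass(config))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the morphology stage
#'
#' For each configured image: channel extraction, background subtraction,
#' pixel export, centred and uncentred pair-correlation (FFT path),
#' decay/oscillation summary, and surface metrics. All intermediate
#' artifacts are written under `output_dir/<image stem>/`: the pixel table
#' and correlation curves as CSV, the mask as PNG, summaries and surface
#' metrics as JSON. Deterministic given the config.
#'
#' @param config A [run_config()] (or anything it accepts) with `images`
#'   set.
#' @return Named list of per-image results (invisibly returns paths in
#'   `$paths`).
#' @export
run_morphology <- function(config) {
  config <- run_config(config)
  if (is.null(config$images)) stop("config$images is required")
  out <- list()
  for (path in config$images) {
    stem <- tools::file_path_sans_ext(basename(path))
    dir <- file.path(config$output_dir, stem)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    res <- tryCatch({
      img <- read_colony_image(path)
      if (is_rgb(img)) img <- extract_channel(img, config$channel)
      bg <- subtract_background(img, strategy = config$background$strategy,
                                threshold = config$background$threshold,
                                k = config$background$k)
      px <- export_pixels(bg$image, bg$mask)
      write_pixel_table(px, file.path(dir, "pixels.csv"))
      png::writePNG(bg$mask * 1, file.path(dir, "mask.png"))
      corr_u <- pair_correlation_fft(bg$image, bg$mask,
                                     bin_width = config$bin_width,
                                     max_r = config$max_r, centered = FALSE)
      corr_c <- pair_correlation_fft(bg$image, bg$mask,
                                     bin_width = config$bin_width,
                                     max_r = config$max_r, centered = TRUE)
      write.csv(as.data.frame(corr_u), file.path(dir, "gamma.csv"),
                row.names = FALSE)
      write.csv(as.data.frame(corr_c), file.path(dir, "gamma_centered.csv"),
                row.names = FALSE)
      summ <- correlation_summary(corr_c)
      surf <- surface_metrics(bg$image, bg$mask, config$calibration)
      .write_json(c(list(image = path), unclass(summ),
                    provenance = list(.run_provenance(config))),
                  file.path(dir, "summary.json"))
      .write_json(unclass(surf)[c("Ra", "Rq", "Rsk", "Rku", "Rt", "SA",
                                  "defined", "n")],
                  file.path(dir, "surface.json"))
      list(pixels = px, correlation = corr_u,
           correlation_centered = corr_c, summary = summ, surface = surf,
           dir = dir)
    }, error = function(e)
      stop("morphology stage failed for image '", path, "': ",
           conditionMessage(e), call. = FALSE))
    out[[stem]] <- res
  }
  out
}

#' Run the fluctuation stage
#'
#' Reads per-culture mutant counts (CSV: `strain`, `culture_id`,
#' `mutant_count`) and final population sizes (CSV: `strain`, `Nt`), fits
#' each strain under the Lea-Coulson model, and writes the rate table and
#' pairwise likelihood-ratio tests to `output_dir`.
#'
#' @param config A [run_config()] with `counts_csv` and `popsize_csv` set.
#' @return The [rate_table()] object.
#' @export
run_fluctuation <- function(config) {
  config <- run_config(config)
  if (is.null(config$counts_csv) || is.null(config$popsize_csv))
    stop("config$counts_csv and config$popsize_csv are required")
  counts <- read.csv(config$counts_csv)
  pops <- read.csv(config$popsize_csv)
  stopifnot(all(c("strain", "mutant_count") %in% names(counts)),
            all(c("strain", "Nt") %in% names(pops)))
  if (nrow(counts) == 0) stop("empty counts file")
  strains <- unique(counts$strain)
  experiments <- lapply(strains, function(s) {
    nt <- pops$Nt[pops$strain == s]
    if (length(nt) == 0) stop("no population size for strain ", s)
    fluctuation_experiment(counts$mutant_count[counts$strain == s],
                           mean(nt))
  })
  names(experiments) <- strains
  comp <- config$comparisons
  if (!is.null(comp)) comp <- lapply(comp, as.character)
  tab <- rate_table(experiments, comparisons = comp, cap = config$cap,
                    ci = TRUE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(tab$estimates, file.path(config$output_dir, "rates.csv"),
            row.names = FALSE)
  if (!is.null(tab$tests))
    write.csv(tab$tests, file.path(config$output_dir, "lrt.csv"),
              row.names = FALSE)
  .write_json(.run_provenance(config),
              file.path(config$output_dir, "fluctuation_provenance.json"))
  tab
}

#' Run the self-validation suite
#'
#' Executes reduced-size oracle-equivalence and recovery checks with the
#' configured seed and writes a pass/fail JSON report: brute-force vs FFT
#' pair-correlation agreement, gamma(0) = 1, simulator vs analytic pmf
#' zero-class agreement, closed-form ML on a one-mutant experiment,
#' wrinkle-wavelength recovery, and competition-fraction recovery.
#'
#' @param config A [run_config()] (seed and output_dir are used).
#' @return A list of check results (each with `pass` and `value`).
#' @export
run_validation <- function(config) {
  config <- run_config(config)
  seed <- config$seed
  checks <- list()
  spec <- colony_spec(image_size = 64, radius = 24, baseline = 100,
                      amplitude = 0, wavelength = 10, noise_sd = 20,
                      background_level = 0, seed = seed)
  img <- sim_random_colony(spec)
  mask <- img$pixels > 0
  bf <- pair_correlation_bruteforce(export_pixels(img, mask), max_r = 20)
  ff <- pair_correlation_fft(img, mask, max_r = 20)
  dev <- max(abs(bf$gamma - ff$gamma), na.rm = TRUE)
  checks$fft_oracle <- list(value = dev, pass = dev <= 1e-9)
  checks$gamma0 <- list(value = ff$gamma[1], pass = ff$gamma[1] == 1)
  m <- 2
  sim <- sim_fluctuation(m / 1e9, 1e9, 2000, seed = seed + 1)
  z <- mean(sim$counts == 0)
  zdev <- abs(z - exp(-m)) / sqrt(exp(-m) * (1 - exp(-m)) / 2000)
  checks$simulator_zero_class <- list(value = z, pass = zdev < 4)
  fit <- fit_mutation_rate(counts = c(0, 0, 0, 1), Nt = 1e8, ci = FALSE)
  checks$ml_closed_form <- list(value = fit$m_hat,
                                pass = abs(fit$m_hat - 0.25) < 1e-6)
  wspec <- colony_spec(image_size = 160, radius = 70, baseline = 120,
                       amplitude = 60, wavelength = 20, noise_sd = 5,
                       background_level = 0, seed = seed + 2)
  wimg <- sim_wrinkled_colony(wspec)
  wcorr <- pair_correlation_fft(wimg, wimg$pixels > 0, max_r = 60,
                                centered = TRUE)
  per <- correlation_summary(wcorr)$oscillation_period
  checks$wavelength_recovery <- list(value = per,
                                     pass = !is.na(per) &&
                                       abs(per - 20) <= 2)
  q <- sim_competition_quartet(0.8, 2, 0.5)
  ab <- relative_abundance(q)
  checks$competition_recovery <- list(value = ab$pct_A,
                                      pass = abs(ab$pct_A - 80) < 1e-9)
  report <- c(list(all_pass = all(vapply(checks, `[[`, TRUE, "pass"))),
              checks, provenance = list(.run_provenance(config)))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  .write_json(report, file.path(config$output_dir, "validation.json"))
  report
}
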