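Package: macromorph
Title: Macrocolony Morphology Metrics and Fluctuation-Assay Mutation Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of bacterial macrocolony phenotypes and
    mutation supply. Computes the normalized radial pair-correlation function
    of masked colony images (exhaustive and FFT-based), intensity-as-height
    surface roughness metrics (Ra, Rq, Rsk, Rku, Rt and the surface-area
    ratio), maximum-likelihood mutation-rate estimates from Luria-Delbruck
    fluctuation assays under the Lea-Coulson model with profile-likelihood
    intervals and a two-sample likelihood-ratio test, fluorescence
    competition-assay normalization, and outgrowth-screening tallies.
    Includes seeded synthetic-data generators (wrinkled colony images,
    Lea-Coulson count vectors, competition quartets, screening records) so
    every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
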