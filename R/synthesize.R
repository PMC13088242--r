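# Synthetic distillate generator: per-fraction concentration distributions,
# Beer-Lambert mixing of Gaussian component bands, instrument-style noise,
# and the methanol spiking protocol used to extend the adulteration range.

#' Per-fraction concentration statistics
#'
#' Reference summary statistics (min, max, mean, SD) of the six quality
#' parameters in each distillation fraction, as determined by GC-FID and
#' titration on a production sample set. These parameterize the truncated
#' normal draws of [sample_concentrations()]. Units: ethanol % v/v; all
#' others mg/100 mL (TA as mg acetic acid/100 mL).
#'
#' @return Tibble with columns `fraction`, `analyte`, `n_ref`, `min`, `max`,
#'   `mean`, `sd`.
#' @export
fraction_distributions <- function() {
  tribble_rows <- list(
    # analyte, fraction, n, min, max, mean, sd
    list("acetaldehyde", "head", 67, 0.44, 112.76, 18.70, 14.34),
    list("acetaldehyde", "body", 87, 0.50, 14.43, 3.58, 3.29),
    list("acetaldehyde", "tail", 26, 0.05, 8.81, 1.30, 1.88),
    list("methanol", "head", 66, 6.59, 50.92, 22.91, 8.62),
    list("methanol", "body", 89, 12.02, 49.26, 28.02, 7.30),
    list("methanol", "tail", 32, 4.80, 41.00, 13.41, 8.31),
    list("ethanol", "head", 67, 36.61, 70.57, 59.41, 5.76),
    list("ethanol", "body", 89, 31.43, 41.21, 36.60, 3.05),
    list("ethanol", "tail", 32, 7.61, 17.14, 12.13, 2.20),
    list("acetic_acid", "head", 62, 6.7, 55.0, 14.4, 12.5),
    list("acetic_acid", "body", 90, 5.6, 81.4, 28.2, 15.4),
    list("acetic_acid", "tail", 32, 1.0, 16.2, 5.7, 3.2),
    list("ta", "head", 15, 14.0, 65.8, 32.9, 15.0),
    list("ta", "body", 65, 7.7, 77.4, 32.0, 16.1),
    list("ta", "tail", 16, 5.8, 9.7, 5.8, 2.4),
    list("furfural", "head", 17, 0.22, 3.43, 0.75, 0.99),
    list("furfural", "body", 84, 0.32, 4.10, 1.62, 0.86),
    list("furfural", "tail", 17, 3.39, 6.31, 5.33, 0.82))
  out <- purrr::map_dfr(tribble_rows, function(r) {
    tibble::tibble(analyte = r[[1]], fraction = r[[2]], n_ref = r[[3]],
                   min = r[[4]], max = r[[5]], mean = r[[6]], sd = r[[7]])
  })
  out[, c("fraction", "analyte", "n_ref", "min", "max", "mean", "sd")]
}

#' Component band library
#'
#' Gaussian band profiles (center, width as Gaussian sigma in cm^-1, height
#' in absorbance per unit concentration) for water and the five spectrally
#' active analytes. Centers sit at the mid-IR assignments of alcohol C-O/C-H
#' stretches (ethanol 1087/1045/879, methanol 1015), the carbonyl/acid bands
#' (1712-1715, 1390, 1275), the acetaldehyde methyl rock (950), the furan
#' ring (1080/1020, 880) and the broad water O-H bands (3350, 1646).
#' Heights are scaled so congener features are one to two orders of
#' magnitude weaker than the ethanol/water features, mirroring mg/100 mL vs
#' percent-level concentrations. Water height is per unit volume fraction.
#'
#' @return Tibble with columns `analyte`, `center`, `width`, `height`.
#' @export
component_library <- function() {
  bands <- list(
    water        = list(c(3350, 250, 0.90), c(1646, 40, 0.35)),
    ethanol      = list(c(2974, 18, 4.0e-3), c(2928, 16, 3.5e-3),
                        c(2886, 18, 3.0e-3), c(1087, 14, 6.0e-3),
                        c(1045, 12, 7.0e-3), c(879, 12, 2.5e-3)),
    methanol     = list(c(2944, 18, 1.5e-3), c(2833, 16, 1.2e-3),
                        c(1015, 12, 2.5e-3)),
    acetaldehyde = list(c(1715, 16, 2.0e-3), c(950, 14, 2.5e-3)),
    acetic_acid  = list(c(1712, 16, 2.0e-3), c(1390, 18, 1.5e-3),
                        c(1275, 16, 2.0e-3)),
    furfural     = list(c(1670, 14, 2.0e-3), c(1080, 12, 2.0e-3),
                        c(1020, 12, 1.5e-3), c(880, 10, 2.5e-3)))
  purrr::map_dfr(names(bands), function(a) {
    purrr::map_dfr(bands[[a]], function(b) {
      tibble::tibble(analyte = a, center = b[1], width = b[2], height = b[3])
    })
  })
}

#' Instrument noise configuration
#'
#' @param additive_sd SD of white absorbance noise per channel.
#' @param offset_range Baseline offset drawn uniformly in +/- this value.
#' @param slope_range Baseline slope (absorbance per cm^-1), uniform in +/-.
#' @param gain_sd SD of the per-sample multiplicative gain around 1.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(additive_sd = 5e-4, offset_range = 2e-3,
                         slope_range = 1e-6, gain_sd = 0.01) {
  stopifnot(additive_sd >= 0, offset_range >= 0, slope_range >= 0, gain_sd >= 0)
  structure(list(additive_sd = additive_sd, offset_range = offset_range,
                 slope_range = slope_range, gain_sd = gain_sd),
            class = "noise_config")
}

#' Zero-noise configuration (exactly linear synthesis)
#' @return A `noise_config` with every magnitude set to 0.
#' @export
noise_off <- function() noise_config(0, 0, 0, 0)

# Truncated normal by rejection; errors if the window is effectively
# unreachable from N(mean, sd).
rtruncnorm_reject <- function(n, mean, sd, lo, hi, max_rounds = 1000) {
  if (n == 0) return(numeric(0))
  out <- numeric(0)
  for (i in seq_len(max_rounds)) {
    draw <- rnorm(2L * max(n - length(out), 8L), mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  abort(sprintf("truncated-normal rejection failed for [%g, %g] around %g",
                lo, hi, mean), class = "spiritspec_sampling_error")
}

#' Draw per-sample analyte concentrations for a fraction
#'
#' Ethanol and the four congeners are drawn independently from normal
#' distributions with the fraction's reference mean/SD, truncated by
#' rejection to the fraction's observed [min, max]. Titratable acidity is
#' derived as 1.1 x acetic acid plus a small measurement-scale noise
#' (truncated at 0): TA has no spectral identity of its own and co-varies
#' with the acids.
#'
#' @param fraction One of `"head"`, `"body"`, `"tail"`.
#' @param n Number of samples.
#' @param dist Distribution table in the format of [fraction_distributions()].
#' @param seed Optional integer seed (draws are reproducible under it).
#' @param ta_noise_sd SD of the TA derivation noise (mg/100 mL).
#' @return Tibble of metadata rows ([meta_columns()]) with all six
#'   concentrations populated and `fraction` assigned.
#' @export
sample_concentrations <- function(fraction, n, dist = fraction_distributions(),
                                  seed = NULL, ta_noise_sd = 1.5) {
  stopifnot(n >= 0, fraction %in% fraction_levels())
  if (!is.null(seed)) set.seed(seed)
  d <- dist[dist$fraction == fraction, ]
  sampled <- c("ethanol", "methanol", "acetaldehyde", "acetic_acid", "furfural")
  draws <- purrr::map(sampled, function(a) {
    row <- d[d$analyte == a, ]
    if (nrow(row) != 1) {
      abort(sprintf("distribution table lacks %s/%s", fraction, a),
            class = "spiritspec_sampling_error")
    }
    rtruncnorm_reject(n, row$mean, row$sd, row$min, row$max)
  })
  names(draws) <- sampled
  ta <- pmax(0, 1.1 * draws$acetic_acid + rnorm(n, 0, ta_noise_sd))
  tibble::tibble(
    sample_id = if (n > 0) sprintf("%s_%03d", fraction, seq_len(n)) else character(0),
    fraction = rep(fraction, n),
    variety = rep("synthetic", n),
    ethanol_pct = draws$ethanol,
    methanol_mg100 = draws$methanol,
    acetaldehyde_mg100 = draws$acetaldehyde,
    acetic_mg100 = draws$acetic_acid,
    furfural_mg100 = draws$furfural,
    ta_mg100 = ta)
}

#' Append methanol-spiked samples
#'
#' Emulates the adulteration protocol: `n_spiked` distinct source samples
#' are cloned and each clone's methanol is raised by a dose drawn uniformly
#' in `dose_range` (mg/100 mL); every dose is distinct, so every spiked
#' sample carries a unique methanol concentration. New ids get a `_spk`
#' suffix.
#'
#' @param conc Concentration table (metadata tibble).
#' @param n_spiked Number of samples to spike (default 20).
#' @param dose_range Length-2 numeric `(lo, hi)` in mg/100 mL, default 50-70.
#' @param seed Optional integer seed.
#' @return The table with `n_spiked` additional rows appended.
#' @export
spike_methanol <- function(conc, n_spiked = 20, dose_range = c(50, 70),
                           seed = NULL) {
  stopifnot(length(dose_range) == 2, dose_range[1] < dose_range[2])
  if (n_spiked == 0) return(conc)
  if (n_spiked > nrow(conc)) {
    abort("n_spiked exceeds the number of source samples",
          class = "spiritspec_argument_error")
  }
  if (!is.null(seed)) set.seed(seed)
  src <- sample(nrow(conc), n_spiked)
  repeat {
    doses <- runif(n_spiked, dose_range[1], dose_range[2])
    if (!anyDuplicated(doses)) break
  }
  spiked <- conc[src, ]
  spiked$methanol_mg100 <- spiked$methanol_mg100 + doses
  spiked$sample_id <- sprintf("%s_spk%02d", spiked$sample_id, seq_len(n_spiked))
  dplyr::bind_rows(conc, spiked)
}

# Unit spectra (one row per component incl. water) on a grid.
unit_spectra <- function(lib, grid, scale = 1) {
  comps <- unique(lib$analyte)
  u <- matrix(0, length(comps), length(grid), dimnames = list(comps, NULL))
  for (i in seq_len(nrow(lib))) {
    b <- lib[i, ]
    u[b$analyte, ] <- u[b$analyte, ] +
      scale * b$height * exp(-(grid - b$center)^2 / (2 * b$width^2))
  }
  u
}

#' Synthesize ATR-FTIR spectra from a concentration table
#'
#' Near-linear Beer-Lambert mixing: for each sample,
#' `A(v) = gain * (sum_analyte c * unit(v) + w_water * water(v)) +
#' offset + slope * (v - mid) + eps(v)`, with water volume weight
#' `w_water = 1 - ethanol/100`. With `noise = noise_off()` the output is
#' exactly affine in the concentration vector.
#'
#' @param conc Concentration table (all six concentrations populated).
#' @param lib Component library ([component_library()]).
#' @param noise A [noise_config()].
#' @param grid Wavenumber grid (descending).
#' @param seed Optional integer seed for the noise draws.
#' @param water Include the water background (weight `1 - ethanol/100`)?
#' @return A [spectra_set()] carrying `conc` as metadata.
#' @export
synthesize_spectra <- function(conc, lib = component_library(),
                               noise = noise_config(), grid = default_grid(),
                               seed = NULL, water = TRUE) {
  cols <- analyte_columns()
  spectral <- setdiff(names(cols), "ta")
  missing_lib <- setdiff(c(spectral, if (water) "water"), unique(lib$analyte))
  if (length(missing_lib)) {
    abort(sprintf("component library lacks: %s",
                  paste(missing_lib, collapse = ", ")),
          class = "spiritspec_configuration_error")
  }
  if (anyNA(conc[, unname(cols)])) {
    abort("all concentrations must be populated for synthesis",
          class = "spiritspec_configuration_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(conc)
  u <- unit_spectra(lib, grid)
  cmat <- as.matrix(conc[, unname(cols[spectral]), drop = FALSE])
  colnames(cmat) <- spectral
  if (water) {
    cmat <- cbind(cmat, water = 1 - conc$ethanol_pct / 100)
  }
  a <- cmat %*% u[colnames(cmat), , drop = FALSE]
  gain <- 1 + rnorm(n, 0, noise$gain_sd)
  offset <- runif(n, -noise$offset_range, noise$offset_range)
  slope <- runif(n, -noise$slope_range, noise$slope_range)
  baseline <- outer(offset, rep(1, length(grid))) +
    outer(slope, grid - mean(grid))
  eps <- matrix(rnorm(n * length(grid), 0, noise$additive_sd), n)
  spectra_set(a * gain + baseline + eps, grid, conc)
}

#' Simulate a full labeled distillate study
#'
#' Convenience wrapper: draws concentrations for the three fractions,
#' optionally applies the methanol spiking protocol, and synthesizes
#' spectra. Child seeds are derived from `seed` by fixed offsets so each
#' stage is independently reproducible.
#'
#' @param n_head,n_body,n_tail Samples per fraction (defaults mirror the
#'   reference study: 67/89/32).
#' @param seed Integer seed.
#' @param noise A [noise_config()].
#' @param spike_n,spike_range Methanol spiking settings (0 disables).
#' @param lib,grid Component library and wavenumber grid.
#' @return A [spectra_set()].
#' @export
simulate_distillates <- function(n_head = 67, n_body = 89, n_tail = 32,
                                 seed = 1, noise = noise_config(),
                                 spike_n = 0, spike_range = c(50, 70),
                                 lib = component_library(),
                                 grid = default_grid()) {
  conc <- dplyr::bind_rows(
    sample_concentrations("head", n_head, seed = seed + 101L),
    sample_concentrations("body", n_body, seed = seed + 102L),
    sample_concentrations("tail", n_tail, seed = seed + 103L))
  if (spike_n > 0) {
    conc <- spike_methanol(conc, spike_n, spike_range, seed = seed + 104L)
  }
  synthesize_spectra(conc, lib = lib, noise = noise, grid = grid,
                     seed = seed + 105L)
}
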