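test_that("concentration sampler respects the reference bounds and mean", {
  conc <- sample_concentrations("body", 2000, seed = 5)
  e <- conc$ethanol_pct
  expect_true(all(e >= 31.43 & e <= 41.21))
  expect_lt(abs(mean(e) - 36.60), 0.3)
  # determinism under a fixed seed
  expect_identical(conc, sample_concentrations("body", 2000, seed = 5))
  expect_equal(nrow(sample_concentrations("head", 0, seed = 1)), 0)
})

test_that("sampled analytes stay inside their fraction's range with the right mean", {
  dist <- fraction_distributions()
  sampled <- c("ethanol", "methanol", "acetaldehyde", "acetic_acid", "furfural")
  cols <- analyte_columns()
  for (fr in c("head", "body", "tail")) {
    conc <- sample_concentrations(fr, 400, seed = 11)
    for (a in sampled) {
      d <- dist[dist$fraction == fr & dist$analyte == a, ]
      v <- conc[[cols[[a]]]]
      expect_true(all(v >= d$min & v <= d$max),
                  label = sprintf("%s/%s in bounds", fr, a))
      # analytic truncated-normal mean as the oracle
      al <- (d$min - d$mean) / d$sd
      be <- (d$max - d$mean) / d$sd
      mu_tr <- d$mean + d$sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
      var_tr <- d$sd^2 * (1 + (al * dnorm(al) - be * dnorm(be)) /
                            (pnorm(be) - pnorm(al)) -
                          ((dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al)))^2)
      se <- sqrt(var_tr / 400)
      expect_lt(abs(mean(v) - mu_tr), 3 * se + 1e-12)
    }
  }
})

test_that("methanol spiking appends distinct doses in range", {
  conc <- sample_concentrations("body", 100, seed = 2)
  spiked <- spike_methanol(conc, 20, c(50, 70), seed = 9)
  expect_equal(nrow(spiked), 120)
  doses <- spiked$methanol_mg100[101:120] -
    conc$methanol_mg100[match(sub("_spk\\d+$", "", spiked$sample_id[101:120]),
                              conc$sample_id)]
  expect_true(all(doses >= 50 & doses <= 70))
  for (i in seq_along(doses)) {       # exhaustive pairwise distinctness
    for (j in seq_along(doses)) {
      if (i != j) expect_true(doses[i] != doses[j])
    }
  }
  expect_identical(spike_methanol(conc, 20, c(50, 70), seed = 9), spiked)
  expect_identical(spike_methanol(conc, 0), conc)
  expect_error(spike_methanol(conc, 101), class = "spiritspec_argument_error")
})

test_that("noiseless synthesis is exactly affine in the concentrations", {
  grid <- seq(1400, 800, by = -2)
  base <- sample_concentrations("body", 1, seed = 1)
  zero <- base
  zero[unname(analyte_columns())] <- 0
  s0 <- synthesize_spectra(zero, noise = noise_off(), grid = grid,
                           water = FALSE)
  expect_true(all(absorbance(s0) == 0))

  one <- zero
  one$acetaldehyde_mg100 <- 3
  two <- zero
  two$acetaldehyde_mg100 <- 6
  a1 <- absorbance(synthesize_spectra(one, noise = noise_off(), grid = grid,
                                      water = FALSE))
  a2 <- absorbance(synthesize_spectra(two, noise = noise_off(), grid = grid,
                                      water = FALSE))
  expect_identical(a2, 2 * a1)  # doubling oracle by direct subtraction

  # finite-difference sensitivity equals the unit spectrum exactly
  lib <- component_library()
  unit <- spiritspec:::unit_spectra(lib, grid)["acetaldehyde", ]
  expect_equal(as.numeric(a2 - a1) / 3, unit, tolerance = 1e-12)

  expect_error(
    synthesize_spectra(base, lib = lib[lib$analyte != "furfural", ],
                       noise = noise_off(), grid = grid),
    class = "spiritspec_configuration_error")
})

test_that("body mean spectrum has the ethanol C-O maxima near 1045 and 1087", {
  dist <- fraction_distributions()
  body <- dist[dist$fraction == "body", ]
  conc <- sample_concentrations("body", 1, seed = 1)
  for (a in c("ethanol", "methanol", "acetaldehyde", "acetic_acid", "furfural")) {
    conc[[analyte_columns()[[a]]]] <- body$mean[body$analyte == a]
  }
  s <- synthesize_spectra(conc, noise = noise_off())
  wn <- wavenumbers(s)
  ab <- as.numeric(absorbance(s))
  is_local_max <- c(FALSE, diff(sign(diff(ab))) == -2, FALSE)
  peaks <- wn[is_local_max]
  expect_true(any(abs(peaks - 1045) <= 4))
  expect_true(any(abs(peaks - 1087) <= 4))
})

test_that("the full simulation is deterministic under a fixed seed", {
  s1 <- simulate_distillates(5, 6, 4, seed = 8, spike_n = 2)
  s2 <- simulate_distillates(5, 6, 4, seed = 8, spike_n = 2)
  expect_identical(absorbance(s1), absorbance(s2))
  expect_identical(tibble::as_tibble(s1)[meta_columns()],
                   tibble::as_tibble(s2)[meta_columns()])
})
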