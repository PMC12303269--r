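test_that("null attenuation reproduces baseline + lamp profile exactly", {
  cfg <- synthetic_config(
    n_patients = 2, samples_per_patient = 2, seed = 3,
    peaks = default_peaks()[0, ], patient_effect_sd = 0,
    sample_scatter_sd = 0, noise_sd = 0, patient_lab_sd = 0)
  co <- simulate_cohort(cfg)
  wl <- unclass(cfg$grid)
  I0 <- cfg$lamp$amplitude * exp(-(wl - cfg$lamp$center)^2 /
                                   (2 * cfg$lamp$width^2))
  for (cb in co$cubes)
    for (p in c("DT", "AT", "AR")) {
      expected <- pmin(cfg$pathway_gain[[p]] * I0 + cfg$baseline_offset,
                       cfg$ceiling)
      expect_equal(unname(cb$spectra[p, ]), expected)
    }
})

test_that("the same seed reproduces the cohort bit-for-bit", {
  cfg <- synthetic_config(n_patients = 10, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth$concentrations, b$truth$concentrations)
  expect_identical(lapply(a$cubes, `[[`, "spectra"),
                   lapply(b$cubes, `[[`, "spectra"))
  c2 <- simulate_cohort(synthetic_config(n_patients = 10, seed = 43))
  expect_false(identical(a$truth$concentrations, c2$truth$concentrations))
})

test_that("a planted hemoglobin band at 586 nm correlates negatively, |r| > 0.6", {
  co <- single_peak_cohort()  # 100 patients x 4 samples = 400
  ch <- nearest_channel(586)
  m <- snv_matrix(spectra_matrix(co$cubes, "DT"))
  hb <- co$lab$hemoglobin[match(rownames(m), co$lab$sample_id)]
  pr <- pearson_with_p(m[, ch + 1], hb)
  expect_lt(pr$r, -0.6)
  expect_lt(pr$p, 1e-6)
})

test_that("zero-inflation matches the configured point mass within binomial error", {
  co <- study_cohort()
  am <- default_analyte_models()
  for (a in c("hemoglobin", "erythrocytes")) {
    p0 <- am$zero_mass[am$analyte == a]
    n <- nrow(co$lab)
    obs <- mean(co$lab[[a]] == 0)
    expect_lt(abs(obs - p0), 3 * sqrt(p0 * (1 - p0) / n))
  }
  expect_true(all(co$lab$triglycerides > 0))
})

test_that("SNV collapses scatter-dominated per-wavelength SD by > 2 orders of magnitude", {
  cfg <- synthetic_config(n_patients = 60, samples_per_patient = 3, seed = 9,
                          sample_scatter_sd = 1, noise_sd = 5,
                          lamp = list(center = 595, width = 150,
                                      amplitude = 15000))
  co <- simulate_cohort(cfg)
  m <- spectra_matrix(co$cubes, "AT")
  ratio <- per_wavelength_sd(m)$mean_sd / per_wavelength_sd(snv_matrix(m))$mean_sd
  expect_gt(ratio, 100)
})

test_that("correlation screening localises each planted peak within 2 channels", {
  peaks <- data.frame(analyte = c("hemoglobin", "bilirubin"),
                      center_nm = c(586, 470), width_nm = c(12, 18),
                      strength = c(0.22, 0.18))
  co <- simulate_cohort(planted_config(peaks, seed = 5))
  for (i in 1:2) {
    cv <- build_curves(co$cubes, co$lab, peaks$analyte[i], pathways = "DT")
    expect_lte(abs(cv$channel[which.min(cv$r)] -
                     nearest_channel(peaks$center_nm[i])), 2)
    expect_lt(min(cv$r, na.rm = TRUE), -0.5)
  }
})

test_that("saturated fraction grows monotonically with lamp amplitude", {
  fracs <- vapply(c(20000, 40000, 80000), function(amp) {
    cfg <- synthetic_config(n_patients = 20, samples_per_patient = 2,
                            seed = 13,
                            lamp = list(center = 595, width = 150,
                                        amplitude = amp))
    co <- simulate_cohort(cfg)
    mean(vapply(co$cubes, function(cb) mean(saturation_mask(cb)), 0))
  }, 0)
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[3], fracs[1])
})

test_that("degenerate configs are rejected", {
  expect_error(synthetic_config(n_patients = 0), "at least one patient")
  expect_error(synthetic_config(noise_sd = -1), "SDs")
  expect_error(synthetic_config(
    peaks = data.frame(analyte = "hemoglobin", center_nm = 900,
                       width_nm = 10, strength = 1)), "outside")
})
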