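# Synthetic cohort generator. The forward model is Beer-Lambert attenuation of
# a broad lamp profile: transmitted intensity at wavelength w for sample s of
# patient p through pathway q is
#   I(w) = clip( gain_q * g_ps * I0(w) * 10^(-A(w)) + baseline + noise, 0, 65000 )
#   A(w) = sum_a strength_a * gauss(w; center_a, width_a) * conc_a * pathscale_q
#   g_ps = exp(patient intercept + sample scatter)     (multiplicative scatter)
# Analyte concentrations are zero-inflated log-normals with a per-patient
# location shift, so repeated samples from one patient are correlated both in
# their spectra and in their laboratory values.

#' Default per-analyte concentration models
#'
#' Zero-inflated log-normal parameters per analyte. The point masses at zero
#' for hemoglobin, erythrocytes and the cell counts mirror the fraction of
#' drain samples with no detectable marker; the log-normal bodies give
#' right-skewed concentrations on the scale of each analyte's unit.
#' `shared_loading` couples an analyte's log-concentration to a per-sample
#' latent severity factor: hemoglobin and erythrocytes load it strongly
#' (free hemoglobin in a drain comes from lysed red cells), so their
#' concentrations are correlated as in real bloody effluent.
#'
#' @return data.frame with columns `analyte`, `meanlog`, `sdlog`,
#'   `zero_mass`, `shared_loading`.
#' @export
default_analyte_models <- function() {
  data.frame(
    analyte = drain_analytes(),
    meanlog = log(c(1.5, 20, 0.7, 2.5, 60, 4, 300, 25, 0.2, 1, 1, 0.5, 1, 50)),
    sdlog = c(0.7, 1, 1.2, 0.5, 0.6, 0.6, 0.7, 1, 1, 0.8, 1, 1, 1, 0.9),
    zero_mass = c(0, 0, 0, 0, 0, 0, 0, 0, 0.138, 0.333, 0.01, 0.083, 0.02, 0),
    shared_loading = c(0, 0, 0, 0.3, 0, 0, 0.3, 0, 0.85, 0.85, 0.2, 0.2,
                       0.2, 0),
    stringsAsFactors = FALSE
  )
}

#' Default analyte absorption peaks
#'
#' Gaussian absorptivity profiles (peak absorbance per concentration unit).
#' Hemoglobin carries its literature visible-range bands (586/557/514 nm,
#' shared with erythrocytes at 586 nm); glucose, the enzymes and the cell
#' counts absorb outside the visible range and get no peak, so screening
#' finds nothing for them.
#'
#' @return data.frame with columns `analyte`, `center_nm`, `width_nm`,
#'   `strength`.
#' @export
default_peaks <- function() {
  data.frame(
    analyte = c("hemoglobin", "hemoglobin", "hemoglobin", "erythrocytes",
                "bilirubin", "uric_acid", "ldh", "triglycerides",
                "albumin", "total_protein"),
    center_nm = c(586, 557, 514, 586, 470, 354, 659, 667, 580, 535),
    width_nm = c(12, 10, 12, 12, 25, 15, 20, 40, 30, 30),
    strength = c(0.25, 0.12, 0.10, 0.8, 0.15, 0.05, 6e-4, 2e-3, 0.08, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions: 180 patients contributing 1--5
#' samples each (~540 samples), three pathways, detector ceiling 65000.
#'
#' @param n_patients number of patients.
#' @param samples_per_patient integer vector sampled uniformly per patient.
#' @param seed RNG seed; a fixed seed makes the cohort bit-reproducible.
#' @param analyte_models data.frame as [default_analyte_models()].
#' @param peaks data.frame as [default_peaks()].
#' @param patient_effect_sd SD of the per-patient log-intensity intercept.
#' @param patient_lab_sd SD of the per-patient analyte log-location shift.
#' @param sample_scatter_sd SD of the per-measurement log multiplicative
#'   scatter (what SNV removes).
#' @param baseline_offset additive counts.
#' @param noise_sd additive Gaussian detector noise (counts).
#' @param lamp list(center, width, amplitude): Gaussian lamp profile I0.
#' @param pathway_gain multiplicative intensity gain per pathway.
#' @param pathway_scale path-length multiplier on absorbance per pathway.
#' @param ceiling detector saturation level.
#' @param grid `wavelength_grid`.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 180L,
                             samples_per_patient = 1:5,
                             seed = 1L,
                             analyte_models = default_analyte_models(),
                             peaks = default_peaks(),
                             patient_effect_sd = 0.3,
                             patient_lab_sd = 0.4,
                             sample_scatter_sd = 0.5,
                             baseline_offset = 500,
                             noise_sd = 30,
                             lamp = list(center = 595, width = 150,
                                         amplitude = 28000),
                             pathway_gain = c(DT = 1, AT = 0.9, AR = 0.5),
                             pathway_scale = c(DT = 1, AT = 1.2, AR = 0.7),
                             ceiling = INTENSITY_CEILING,
                             grid = wavelength_grid()) {
  if (n_patients < 1L) stop("need at least one patient", call. = FALSE)
  sds <- c(patient_effect_sd, patient_lab_sd, sample_scatter_sd, noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  wl <- unclass(grid)
  if (nrow(peaks) && (any(peaks$center_nm < wl[1]) ||
                      any(peaks$center_nm > wl[length(wl)])))
    stop("peak center outside the wavelength grid", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a patient-structured cohort of spectra and laboratory panels
#'
#' @param config `synthetic_config`.
#' @return list with `cubes` (list of `spectral_cube`), `lab` (`lab_table`),
#'   and `truth` (latent concentrations, patient intercepts, scatter draws)
#'   for recovery tests.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  wl <- unclass(config$grid)
  n_ch <- length(wl)
  lamp <- config$lamp
  I0 <- lamp$amplitude * exp(-(wl - lamp$center)^2 / (2 * lamp$width^2))
  am <- config$analyte_models
  pk <- config$peaks
  # absorptivity profiles, one row per peak
  prof <- if (nrow(pk))
    t(vapply(seq_len(nrow(pk)), function(i)
      pk$strength[i] * exp(-(wl - pk$center_nm[i])^2 / (2 * pk$width_nm[i]^2)),
      numeric(n_ch)))
  else matrix(0, 0, n_ch)

  n_per <- sample(config$samples_per_patient, config$n_patients, replace = TRUE)
  pid <- sprintf("P%03d", seq_len(config$n_patients))
  u_patient <- setNames(rnorm(config$n_patients, 0, config$patient_effect_sd), pid)
  w_lab <- matrix(rnorm(config$n_patients * nrow(am), 0, config$patient_lab_sd),
                  config$n_patients, nrow(am), dimnames = list(pid, am$analyte))

  samp_pid <- rep(pid, n_per)
  n_samp <- length(samp_pid)
  sid <- sprintf("S%04d", seq_len(n_samp))

  loading <- if ("shared_loading" %in% names(am)) am$shared_loading
             else rep(0, nrow(am))
  z_shared <- rnorm(n_samp)  # latent per-sample severity factor
  conc <- matrix(0, n_samp, nrow(am), dimnames = list(sid, am$analyte))
  for (j in seq_len(nrow(am))) {
    nonzero <- rbinom(n_samp, 1, 1 - am$zero_mass[j]) == 1
    rho <- loading[j]
    eps <- rho * z_shared[nonzero] + sqrt(1 - rho^2) * rnorm(sum(nonzero))
    conc[nonzero, j] <- exp(am$meanlog[j] + w_lab[samp_pid, j][nonzero] +
                              am$sdlog[j] * eps)
  }

  scatter <- matrix(rnorm(n_samp * 3L, 0, config$sample_scatter_sd),
                    n_samp, 3L, dimnames = list(sid, PATHWAYS))
  cubes <- vector("list", n_samp)
  for (i in seq_len(n_samp)) {
    m <- matrix(NA_real_, 3L, n_ch, dimnames = list(PATHWAYS, NULL))
    for (q in PATHWAYS) {
      A <- if (nrow(pk))
        colSums(prof * (conc[i, pk$analyte] * config$pathway_scale[[q]]))
      else rep(0, n_ch)
      g <- exp(u_patient[[samp_pid[i]]] + scatter[i, q])
      raw <- config$pathway_gain[[q]] * g * I0 * 10^(-A) +
        config$baseline_offset + rnorm(n_ch, 0, config$noise_sd)
      m[q, ] <- pmin(pmax(raw, 0), config$ceiling)
    }
    cubes[[i]] <- spectral_cube(sid[i], samp_pid[i], m, grid = config$grid)
  }

  lab <- lab_table(sid, samp_pid, as.data.frame(conc))
  list(cubes = cubes, lab = lab,
       truth = list(concentrations = conc, patient_intercept = u_patient,
                    patient_lab_shift = w_lab, scatter = scatter,
                    config = config))
}

#' Write a simulated cohort in canonical and deposited-workbook layouts
#'
#' Emits `spectra_long.csv`, `spectra_wide.csv` and `lab.csv` (canonical
#' dialects), an S3-shaped file `s3_shaped_synthetic.csv` (supplement
#' dialect), and an S4-shaped single-analyte file
#' `s4_shaped_<analyte>_synthetic.csv` with binary label, laboratory value,
#' patient id and SNV intensities at the named wavelengths.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param s4_analyte analyte for the S4-shaped file.
#' @param s4_wavelengths named numeric vector, names = pathways, values = nm.
#' @return named character vector of file paths, invisibly.
#' @export
emit_supplement_layout <- function(cohort, dir,
                                   s4_analyte = "hemoglobin",
                                   s4_wavelengths = c(DT = 342.41, AT = 363.92,
                                                      AR = 557.5, DT = 586.83)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(long = file.path(dir, "spectra_long.csv"),
             wide = file.path(dir, "spectra_wide.csv"),
             lab = file.path(dir, "lab.csv"),
             s3 = file.path(dir, "s3_shaped_synthetic.csv"),
             s4 = file.path(dir, paste0("s4_shaped_", s4_analyte,
                                        "_synthetic.csv")))
  write_spectra_csv(cohort$cubes, paths["long"], "long")
  write_spectra_csv(cohort$cubes, paths["wide"], "wide")
  write_lab_csv(cohort$lab, paths["lab"])

  lab_df <- as.data.frame(cohort$lab)
  join <- function(v) paste(format(v, trim = TRUE, scientific = FALSE,
                                   digits = 15), collapse = ";")
  s3 <- data.frame(
    patient_id = vapply(cohort$cubes, `[[`, character(1), "patient_id"),
    sample_id = vapply(cohort$cubes, `[[`, character(1), "sample_id"),
    DT = vapply(cohort$cubes, function(cb) join(cb$spectra["DT", ]), ""),
    AT = vapply(cohort$cubes, function(cb) join(cb$spectra["AT", ]), ""),
    AR = vapply(cohort$cubes, function(cb) join(cb$spectra["AR", ]), ""),
    stringsAsFactors = FALSE)
  s3 <- merge(s3, lab_df[c("sample_id", intersect(names(lab_df),
                                                  drain_analytes()))],
              by = "sample_id", sort = FALSE)
  s3 <- s3[c("patient_id", "sample_id", PATHWAYS,
             intersect(names(s3), drain_analytes()))]
  write.csv(s3, paths["s3"], row.names = FALSE, na = "")

  grid <- if (length(cohort$cubes)) cohort$cubes[[1]]$grid else wavelength_grid()
  ch <- nearest_channel(s4_wavelengths, grid)
  feat_names <- sprintf("%s_%.2fnm", names(s4_wavelengths),
                        map_channel_to_wavelength(ch, grid))
  cut <- default_cutoffs()
  cutoff <- cut$cutoff[cut$analyte == s4_analyte]
  if (length(cohort$cubes)) {
    feats <- sapply(seq_along(s4_wavelengths), function(k) {
      m <- spectra_matrix(cohort$cubes, names(s4_wavelengths)[k],
                          drop_missing = FALSE)
      snv_matrix(m)[, ch[k] + 1L]
    })
    if (!is.matrix(feats)) feats <- matrix(feats, nrow = 1L)
    colnames(feats) <- feat_names
    ord <- match(vapply(cohort$cubes, `[[`, character(1), "sample_id"),
                 lab_df$sample_id)
    s4 <- cbind(data.frame(binary = as.integer(lab_df[[s4_analyte]][ord] > cutoff),
                           lab_value = lab_df[[s4_analyte]][ord],
                           patient_id = lab_df$patient_id[ord]),
                as.data.frame(feats))
  } else {
    s4 <- as.data.frame(c(list(binary = integer(), lab_value = numeric(),
                               patient_id = character()),
                          setNames(rep(list(numeric()),
                                       length(feat_names)), feat_names)))
  }
  write.csv(s4, paths["s4"], row.names = FALSE, na = "")
  invisible(paths)
}
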