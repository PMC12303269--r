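# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

# small cohort for plumbing tests
small_cohort <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulate_cohort(synthetic_config(n_patients = 30,
                                                        seed = 7))
  .fixtures$small
}

# study-scale cohort (~180 patients / ~520 samples) for the heavier checks
study_cohort <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- simulate_cohort(synthetic_config(seed = 7))
  .fixtures$study
}

# Planted-signal construction for the screening oracles: a flat lamp, no
# scatter, bounded concentrations and detector noise sized so the planted
# absorption bands give Pearson r around -0.7 -- the linear Beer-Lambert
# regime where the correlation extremum sits at the band centre.
planted_config <- function(peaks, seed = 5L, noise_sd = 3500) {
  am <- default_analyte_models()
  am$sdlog[] <- 0.25
  am$zero_mass[am$analyte == "bilirubin"] <- 0.3
  synthetic_config(
    n_patients = 100L, samples_per_patient = 4L, seed = seed,
    analyte_models = am, peaks = peaks,
    patient_effect_sd = 0, patient_lab_sd = 0, sample_scatter_sd = 0,
    noise_sd = noise_sd,
    lamp = list(center = 595, width = 5000, amplitude = 30000))
}

single_peak_config <- function(seed = 5L) {
  planted_config(data.frame(analyte = "hemoglobin", center_nm = 586,
                            width_nm = 12, strength = 0.22), seed = seed)
}

single_peak_cohort <- function() {
  if (is.null(.fixtures$single))
    .fixtures$single <- simulate_cohort(single_peak_config())
  .fixtures$single
}

# brute-force definitional Pearson r (explicit sums)
pearson_brute <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# brute-force AUC by exhaustive pair enumeration, ties counting 1/2
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
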