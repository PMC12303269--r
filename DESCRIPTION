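Package: drainspec
Title: Spectral Analytics for Surgical Drain Fluid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating visible-range mini-spectrometer readings of
    surgical drain fluid to laboratory analyte concentrations. Implements
    standard normal variate (SNV) spectral preprocessing, per-wavelength
    Pearson correlation screening, censored (Tobit) regression with
    fractional-polynomial covariate transforms and per-patient random
    intercepts, cut-off based logistic classification with and without
    random intercepts, and a five-fold inner/out-of-sample optimism
    correction for MSE, AUC and balanced accuracy. Includes a
    patient-structured synthetic cohort generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
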