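---
title: "Methods: spectral analytics for surgical drain fluid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral analytics for surgical drain fluid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drainspec)
```

## The problem

Post-operative drains produce an effluent whose composition signals
complications: free hemoglobin and erythrocytes indicate bleeding, bilirubin
a bile leak, amylase and lipase a pancreatic fistula, triglycerides a chyle
leak. The reference measurement is a central-laboratory panel, which takes
hours. A visible-range mini-spectrometer (340--850 nm, 288 channels, three
light pathways -- direct transmission DT at 20 µs, angular transmission AT
at 200 µs, angular reflection AR at 320 µs exposure) can read the fluid at
the bedside in seconds. `drainspec` implements the statistical chain that
turns such spectra into analyte estimates and pathology calls, together
with a synthetic cohort generator so the whole chain is testable without
patient data.

## The modelling chain

**1. SNV normalisation.** Raw spectra differ by large multiplicative
scatter (optical coupling, turbidity) and baseline offsets. Each spectrum
$s$ is rescaled to $\tilde s_i = (s_i - \mu(s)) / \sigma(s)$, per sample,
per pathway. We use the sample-SD convention ($n-1$); with 288 points the
difference from the population convention is below 0.2% and is absorbed by
any reproduction tolerance. A constant spectrum is an explicit error, never
a silent `NaN`. Saturated readings (counts at the detector ceiling of
65000) are retained but can be masked out of the SNV statistics via the
`mask` argument; the default leaves them in, because overexposure was
handled upstream by choosing exposure times per pathway rather than by
channel masking.

**2. Correlation screening.** For each analyte and pathway, the SNV
intensity at every channel is correlated with the laboratory value
(Pearson $r$; two-sided $p$ from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df,
pairwise deletion of missing values). Channels with $|r| > 0.3$ and
$p < 0.01$ are candidates; runs of adjacent significant channels collapse
to the local $|r|$ extremum within a ±3-channel window, an implementation
choice -- published analyses report isolated wavelengths without stating
how neighbours were merged. No multiplicity correction is applied across
the 288 × 3 tests: that mirrors the screening practice this package
reproduces, and inflates the family-wise error rate; treat selected
wavelengths as candidates, not confirmed biomarkers. Known literature
wavelengths can be force-included (`force =`), as classification models in
this field commonly do. Wavelengths are resolved to the nearest grid
channel; the default grid is linear over [340, 850] nm because device
calibration polynomials are rarely published -- an explicit 288-value
calibration list overrides it.

**3. Tobit regression with fractional polynomials.** Laboratory
concentrations are non-negative and often stacked at zero (no detectable
marker), so the regression is a left-censored Gaussian (Tobit) model with
the bound at 0 by default (configurable per analyte): uncensored
observations contribute the normal density, censored ones
$\Phi((L - x'\beta)/\sigma)$. Repeated samples from one patient are
correlated; an optional per-patient random intercept is integrated out of
the likelihood by Gauss--Hermite quadrature. Covariates (SNV intensities)
may act nonlinearly, so each is offered the fractional-polynomial ladder
with powers $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ (0 = log; FP2 combines
two, a repeated power $p$ contributing $x^p$ and $x^p\log x$), chosen by
the closed-test sequence: FP2 vs linear on 3 df, then FP2 vs FP1 on 2 df,
at $\alpha = 0.05$, falling back to linear. SNV intensities are negative,
so covariates are first shifted positive (by the smallest distinct-value
gap, floored at 5% of the range so a near-tie cannot park the minimum at
zero, where negative powers would turn it into a leverage point) and
scaled by a power of ten;
out-of-sample values are winsorised to the training transform range, so
log and negative powers stay finite and held-out predictions never
extrapolate beyond the fitted transform.
Backward selection then removes, one at a time, the covariate with the
largest Wald $p > 0.05$ (the selection criterion is our choice; the
procedure we reproduce names backward selection without stating its
criterion). The intercept is never removed.

**4. Classification.** Each analyte is binarised at its pathological
cut-off (a value *strictly above* the cut-off is pathological; for
hemoglobin, erythrocytes and the cell counts the cut-off is 0, since any
presence may indicate bleeding). The greater-than direction is the default
for every analyte but is configurable per analyte, because published
descriptions of the rule conflict with the tabulated pathological
percentages; the percentages are only consistent with "greater than".
Logistic models with (`lme4::glmer`, adaptive Gauss--Hermite) and without
(`stats::glm`) a per-patient random intercept are compared by AUC
(Mann--Whitney form, ties counting ½) and balanced accuracy
((sensitivity + specificity)/2 at a 0.5 probability threshold -- the
threshold used by the reference analysis is unstated, so 0.5 is the
default and configurable).

**5. Optimism correction.** Samples are randomly split into five folds
(samples, not patients, are randomised, mirroring the validation scheme
this package reproduces; a patient-grouped splitter is provided as the
statistically safer option and verified never to split a patient). For
each fold the model is refitted on the remaining 80% and the metric is
recorded on the training data (inner) and the held-out fold (outer). The
corrected global metric is

$$\mathrm{corrected} = \mathrm{global} + \overline{(\mathrm{out} - \mathrm{inner})},$$

one signed formula serving both losses (MSE rises) and scores (AUC/BAC
fall). The sign convention is fixed by reproducing all six columns of the
published regression summary table from their printed components; the
package's worked example (`table3_worked_example()`) recomputes corrected
MSE and $R^2 = 1 - \mathrm{MSE_{corrected}}/\mathrm{Var}(y)$ for every
analyte and reports, rather than hides, the one cell that does not
reproduce (erythrocytes: the identity gives ~0.651 against a printed
0.625; the printed text value of 65.2% suggests a transcription slip in
the table). "Variance" is taken as the sample variance of the response
over the full analysis set, the reading that reproduces the other five
printed $R^2$ values.

Random-intercept models predict for *unseen* patients at the population
level (random effect at its mean of zero) -- the standard mixed-model
prediction for new groups, used for all out-of-fold scoring.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 180 patients
contributing 1--5 samples each (~540 samples against the study's 528 from
181), three pathways, detector ceiling 65000. The forward model is
Beer--Lambert attenuation of a broad Gaussian lamp profile:

$$I(\lambda) = \mathrm{clip}\!\big(g_q\, e^{u_p + e_s}\, I_0(\lambda)\,
10^{-\sum_a k_a(\lambda)\, c_a\, \ell_q} + b + \varepsilon(\lambda),\ 0,\ 65000\big)$$

with per-patient log-intensity intercepts $u_p$, per-measurement
multiplicative scatter $e_s$ (what SNV removes), Gaussian absorptivity
profiles $k_a$ per analyte, pathway gain $g_q$ and path-length $\ell_q$,
baseline $b$ and detector noise $\varepsilon$. Concentrations are
zero-inflated log-normals with a per-patient location shift (so random
effects are detectable on both the spectral and the laboratory side);
hemoglobin and erythrocytes additionally load a shared per-sample severity
factor, since free hemoglobin in a drain comes from lysed red cells.
Default peak placements follow the visible-range literature (hemoglobin
586/557/514 nm, bilirubin in the blue, urate near the UV edge); glucose,
the enzymes and the cell counts get no visible-range band, so screening
correctly returns nothing for them. Scatter and noise magnitudes are
chosen to reproduce the qualitative SNV behaviour (per-wavelength SD
collapsing by orders of magnitude), not device physics: the generator has
no radiometric realism, no wavelength-dependent detector response, no
fluorescence and no turbidity model, so passing tests demonstrate that the
*statistical chain* behaves as specified, not that any device will achieve
the published accuracy on real fluid.

One property of SNV worth knowing when interpreting synthetic results:
because each spectrum is rescaled by its own mean and SD, a single
dominant absorber against a smooth lamp profile can shift the correlation
extremum away from the absorption maximum (the row statistics themselves
depend on concentration). The planted-peak recovery tests therefore use
the linear Beer--Lambert regime (flat lamp, bounded concentrations,
absorbance well below 1), where the extremum provably sits at the band
centre; real multi-absorber spectra are far from the single-absorber
pathological case.

## Numerical choices

- Tobit likelihoods are maximised with BFGS on $(\beta, \log\sigma[,
  \log\tau])$, analytic gradients in the fixed-effects case, and the
  observed-information covariance for Wald tests. Non-convergence is a
  warning plus a flag on the fit, never silent.
- The random intercept is integrated with *fixed* Gauss--Hermite
  quadrature scaled by $\tau$ (21 nodes by default). With 1--6 samples per
  patient and moderate $\tau$ this matches brute-force numerical
  integration to below $10^{-6}$ (verified in the test suite) while
  keeping the likelihood one vectorised expression; adaptive centring
  would only matter for much larger groups.
- Fractional-polynomial search uses a fixed-effects Tobit as the working
  likelihood inside each fold (the transform is selected on training data
  only); the final model adds the random intercept. Backward selection
  acts on the transformed columns.
- Fold assignment, the simulator and every stochastic stage derive their
  RNG state from a single seed; the pipeline derives stage seeds by fixed
  offsets, and reruns are byte-identical for deterministic artifacts.
- Degenerate inputs fail loudly: zero-variance spectra, constant
  laboratory vectors, one-class labels, folds exceeding samples, negative
  laboratory values, intensities outside [0, 65000] (reject or clip, per
  configuration), duplicate (sample, pathway, channel) rows.

## Problem sizes

The test suite and the acceptance script run the full chain at study scale
(~180 patients / ~520 samples) for one analyte -- screening, five-fold
fractional-polynomial Tobit regression with random intercepts, and both
logistic flavours -- which completes in a few minutes on a single core;
the remaining tests use smaller cohorts (30--100 patients) chosen so each
property is still sharply testable.

## Known limitations

- The deposited study data ship as binary workbooks; the readers accept
  the same column layouts as plain CSV (`supplement` dialect, decimal
  commas included), and the reproduction harness
  (`reproduce_supplement()`) runs end-to-end on any file in that layout.
- Device wavelength calibration is approximated as linear over
  [340, 850] nm unless a calibration list is supplied; published channel
  labels such as 342.41 nm are resolved to the nearest grid channel.
- Screening at raw $p < 0.01$ over 864 tests has a material false-positive
  rate at small $n$; the pipeline records every gate so downstream users
  can re-screen stricter.
- Right- or interval-censoring, random slopes and Bayesian estimation are
  out of scope, as are hardware control and raw instrument formats.
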