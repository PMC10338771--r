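---
title: "Margin estimation for tracked moving targets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin estimation for tracked moving targets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptvmargins)
```

## The model

Real-time tumor tracking on a robotic SBRT platform leaves five residual
error sources: segmentation (target delineation between planning images and
live x-rays), deformation (tumor shape/position change relative to the
tracked surrogate), correlation-model error (internal–external model output
versus the x-ray-verified tumor position), prediction error (the
latency-compensating predictor versus the model output), and targeting error
(robot delivery precision, measured by end-to-end tests).

All margin recipes here follow the van Herk dose-population argument: a
margin `2.5Σ` covers systematic (preparation) errors so that 90% of patients
keep ≥95% CTV dose coverage, while random (execution) errors blur the dose
distribution and are covered through the penumbra. With the broad effective
penumbra of lung/abdomen SBRT, the random term is
`β(√(σ² + σρ²) − σρ)` with penumbra width `σρ` and dose-level coefficient
`β`. The five-source extension (`vhf_extended()`) combines systematic SDs in
quadrature and, conventionally, the two log-derived random SDs
independently: `σ² = σ²mod + σ²pred`.

The package's central quantity drops the independence assumption. The model
and prediction residuals are produced by the same tracking chain moments
apart, so error propagation adds their covariance:

`σ²new = σ²mod + σ²pred + 2 Cov`, with `Cov = r · σmod · σpred`.

`mvhf()` inserts this combination into the five-source recipe. Two exact
consequences anchor the test suite: `mvhf` with `Cov = 0` equals
`vhf_extended` identically, and the margin is non-decreasing in `Cov` over
the admissible range `|Cov| ≤ σmod·σpred` (Cauchy–Schwarz), which also
guarantees `σ²new ≥ (σmod − σpred)² ≥ 0`.

## Parameters that matter

| parameter | unit | default | meaning |
|---|---|---|---|
| `sigma_rho` | mm | 6.4 | effective penumbra width for lung/abdomen SBRT |
| `beta` | — | 0.84 | dose-level coefficient (80% prescription isodose) |
| segmentation SD | mm | 0.54 | phantom-study value, isotropic |
| deformation SD | mm | 1.5 / 2.5 | below / above 2 cm peak-to-peak tumor motion |
| E2E SD (G3) | mm | 0.3 isotropic | end-to-end test, older platform |
| E2E SD (VSI) | mm | 0.53 / 0.19 / 0.36 | SI / LR / AP, newer platforms |

The penumbra defaults apply to all sites; they are configurable everywhere
(`sigma_rho`, `beta` arguments and CLI flags) but deliberately not
site-specific. The E2E *mean* offsets are recorded and reported
(`assign_static()$e2e_mean`, `total_tracking_error()`) but do not enter the
margin, which consumes SDs only; whether a systematic E2E bias should be
treated as correctable is a clinical calibration question outside a variance
recipe.

## Estimation conventions

**Systematic vs random.** Per source and direction: a fraction contributes a
mean and a sample SD (denominator n−1; the package standardizes on the
unbiased convention since per-fraction model-error counts are small). The
population systematic SD Σ is the SD over per-patient means (each patient's
mean of fraction means); the random SD σ is the RMS of all fraction SDs.

**Pairing.** Correlation needs time-paired samples, but the streams differ by
three orders of magnitude in cadence. Default `nearest_in_time` pairs each
model sample with the closest prediction sample (ties to the earlier one);
`window_mean` instead uses the mean prediction error since the previous model
update, matching the view that covariance is assessed at model updates. With
a dense prediction stream the two give similar correlations; `nearest` is the
default because it does not average away prediction variability.

**Correlation and covariance.** Pearson r is computed between the paired
samples within a fraction; the covariance is then reconstructed as
`r · σmod · σpred` using the full per-fraction stream SDs. The notation
"correlation between the SDs" that sometimes appears for this construction is
ambiguous; correlating the error series themselves is the reading under
which the covariance both is estimable per fraction and obeys the
Cauchy–Schwarz bound that keeps the margin real. Constant marginals make r
undefined; such estimates propagate as `NA` and are excluded from cohort
averages with a logged count — silently coercing them to zero would bias
cohort covariances toward independence.

**Cohort aggregation.** Per patient, the maximum correlation and covariance
over fractions are extracted first; the cohort value is the mean of the
per-patient maxima. "Maximum" is taken by absolute value with the sign
retained: per-patient covariances are signed, and their partial cancellation
under averaging is precisely the phenomenon of interest — a plain signed
maximum could never produce the negative cohort averages that occur in
practice.

**Distance correlation** (`distance_correlation()`) is the standard
double-centered pairwise-distance V-statistic, in [0, 1], reported as a
nonlinearity diagnostic only. Extending the margin recipe itself to a
nonlinear dependence measure would require rederiving the error propagation
and is out of scope. The implementation is validated against an
independently coded O(n²) brute-force oracle to 1e−10.

## Scenarios

**Adaptive first fraction** (`adaptive_margins()`): fraction 1 is planned
covariance-free; its observed covariance then enters the modified recipe for
every later fraction, whose error components are re-estimated from that
fraction's own streams. The default freezes the covariance itself (the
literal protocol); `freeze = "r"` instead freezes the correlation and
rescales by each later fraction's SDs, which can be preferable when stream
SDs drift between fractions. If the frozen covariance violates the later
fraction's admissibility bound it is projected onto the bound with a
warning — an inevitable consequence of transplanting a covariance across
fractions with different variances.

**Covariance envelope** (`covariance_envelope()`): per patient and direction,
the signed minimum and maximum covariance across fractions, with the
modified margin evaluated at both extremes. Margins are evaluated on
patient-level pooled components (systematic: |mean of fraction means|;
random: RMS of fraction SDs) so that the envelope is a monotone function of
covariance alone; only then does the documented invariant hold that the
envelope brackets every per-fraction margin. Signed (not
magnitude-ordered) extremes are used because relative differences are
reported as signed ranges.

**Per-fraction and per-patient margins.** A single fraction has no
between-patient spread, so its systematic model/prediction component is taken
as the magnitude of its mean error — the natural one-sample analogue of "SD
of means" — with the stream SD as random component. This choice is what makes
per-patient margin distributions (boxplots, F tests) well-defined; it is a
package design decision, not part of the recipe itself.

**F test** (`compare_methods()`): one-way fixed-effects ANOVA across methods'
per-patient margins, the conventional reading of a three-method comparison.
A pairwise variance-ratio F test is exposed separately
(`variance_ratio_test()`) since "F test" is sometimes used in that sense; no
multiple-testing correction is applied, matching raw per-site/direction
reporting. The ANOVA core is validated against `stats::lm`/`anova` and a
textbook between/within oracle, and its null calibration (rejection rate
0.05 ± 0.01 at α = 0.05 over 10⁴ replicates) is part of the acceptance
suite.

## The synthetic generator

`simulate_cohort()` emulates exactly what the estimators consume and nothing
more: per-patient systematic offsets (zero-mean normal, configurable SD per
stream and direction), within-fraction bivariate-normal (model, prediction)
pairs at the model cadence with configurable correlation ρ, marginal
prediction draws on the prediction cadence in between, and the
patient/fraction hierarchy. Defaults mirror the clinical cadences (60 s model,
40 ms prediction) with a 1800 s fraction. Seeding is split per
patient/fraction, so enlarging a cohort never perturbs existing patients.

Deliberately **not** simulated: breathing waveforms, hysteresis, drift,
model-refit transients, heavy tails, or any time-autocorrelation within
streams. Every implemented formula consumes error means, SDs and
cross-correlations only, so a Gaussian, exchangeable-in-time generator spans
the input space the methods can see. Consequently a green simulation test
establishes that the *estimators and recipes* behave as derived — it cannot
establish that clinical tracking errors satisfy the Gaussian or
stationarity assumptions, and real logs with strong nonlinear dependence
(visible as distance correlation well above |Pearson r|) deserve caution.

The two presets place total tracking-error SDs (model ⊕ prediction ⊕ E2E in
quadrature) in the 0.9–1.5 mm band typical of published robotic-SBRT log
analyses, with the lung preset noisier than the liver preset; resulting
margins land at the 4–5 mm scale used clinically for lung targets. Preset
SDs were fixed once from those magnitude targets, before any acceptance
outcome was observed.

## Numerical choices

- Margins are carried at full double precision; report layers round to
  0.01 mm.
- Covariance admissibility is enforced at `|cov| ≤ σmod·σpred + 1e−12`;
  `mvhf()` raises a domain error beyond it, while envelope/adaptive/cohort
  layers project onto the bound with a warning (see above for why projection
  is the right semantics there).
- Distance covariance squared can be numerically slightly negative for
  near-independent data; it is clamped to 0 (independence) before the square
  root.
- Motion amplitude exactly at the 2 cm deformation threshold takes the lower
  branch with a warning; the published rule covers strictly-below and
  strictly-above only.
- Log serialization uses `%.17g`, making write→read→write byte-stable.
- CLI provenance records contain command, version and flags but no
  timestamps, preserving bit-identical reruns under a fixed seed.

## Limitations

- The comparator margin method based on uncertainty-level estimation (UEM)
  is not implemented; `compare_methods()` accepts any named set of
  per-patient margin vectors, so an external implementation slots in as a
  third group.
- Rotational tracking errors are out of scope (fiducial-free lung tracking
  does not correct rotations).
- No dosimetric verification: the recipes are geometric; pseudo-error dose
  reconstruction would be the natural follow-up.
- Adaptive margins are only defined from fraction 2 onward by construction.
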