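# pigmentox

Kinetics and colorimetry of pigment degradation and lipid oxidation in
oil-in-water emulsions.

Natural colorants based on anthocyanins (the red–purple pigments of black
carrot, berries and similar plants) fade during storage of emulsified
foods, and their fading is entangled with the oxidation of the emulsified
oil: the pigments act as radical scavengers and are consumed in the
process. Quantifying this requires fitting two kinds of kinetic model to
replicate storage time series and translating absorbance spectra into
perceptual colour terms. `pigmentox` packages that workflow for food
chemists and formulation scientists:

* **First-order pigment decay** — `fit_decay()` fits
  *C(t) = C₀ e^(−kt)* by bounded nonlinear least squares on the original
  concentration scale and derives the half-life *t₁/₂ = ln 2 / k*.
* **Sigmoidal oxidation kinetics** — `fit_sigmoid()` fits the logistic
  accumulation model
  *c(t) = c_max / (1 + ((c_max − c₀)/c₀) e^(−kt))*
  with multi-start bounded optimisation, and derives the inflection point
  *t\* = ln((c_max − c₀)/c₀)/k* (maximal oxidation rate, concentration
  c_max/2, slope k·c_max/4) and the inflection-tangent induction time
  *t_ind = t\* − 2/k*, reported as absent ("—") when the tangent meets
  the time axis at or below zero.
* **Colorimetry** — turbidity correction *A(522) − A(750)*, sub-grid peak
  location, bathochromic/hypsochromic/hyperchromic shift arithmetic,
  absorbance-spectrum → CIELAB conversion under illuminant C with the
  1931 2° observer, and the full CIEDE2000 colour-difference formula.
* **Quantification** — linear external calibration with inverse
  prediction and extrapolation flags, plus mass-fraction → molarity and
  stock-dose → system-concentration conversions.
* **Synthetic data** — a seeded generator reproducing the replicate
  structure of a storage study (preparations × measurements, lognormal
  preparation effects, truncated Gaussian noise) and pH-dependent pigment
  spectra, so the whole pipeline is testable without lab data.
* **Reporting** — one-way ANOVA with Tukey HSD compact letters and
  `run_pipeline()`, which produces the kinetic-parameter, colour and
  spectral-shift tables end to end, deterministically for a given seed.

All fitting functions return classed S3 objects with the familiar
`print()`, `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
`plot()` and `simulate()` methods.

## Worked example

Simulate a pH 2 storage experiment (2 emulsion preparations × 2
measurements over 21 days), fit each replicate, and aggregate:

```r
library(pigmentox)
cfg    <- kinetic_presets(seed = 42)$pH2_anthocyanin
series <- gen_kinetic_series(cfg)
fits   <- lapply(series, fit_decay)
fits[[1]]
#> First-order decay fit: C(t) = C0 * exp(-k t)
#>   C0 = 24.19 uM, k = 1.582 /day, t_half = 0.4382 days
#>   RSS = 8.773 on 9 observations
aggregate_replicates(fits)
#> Replicate summary (decay_fit, n = 4): anthocyanin, pH 2, dose 0.73 g/L
#>        sample_id pH extract_dose     analyte     model n C0_mean C0_sd k_mean
#>  pH2_anthocyanin  2         0.73 anthocyanin decay_fit 4   24.03 1.028  1.483
#>    k_sd t_half_mean t_half_sd t_half_from_mean_k
#>  0.3627      0.4878    0.1123             0.4674
```

The recovered rate constant (1.48 ± 0.36 day⁻¹ here) scatters around the
generator truth of 1.44 day⁻¹; the summary carries both the mean of the
per-replicate half-lives (0.488 days) and ln 2 over the mean rate
(0.467 days) — the two differ whenever `k` varies between replicates.

Spectral effect of the surfactant at pH 2, and the colour change of a
faded emulsion:

```r
spectral_shift(gen_spectrum(2, with_sds = FALSE, seed = 1),
               gen_spectrum(2, with_sds = TRUE,  seed = 2))
#> Spectral shift: +8.41 nm (bathochromic), +19.7% intensity (1.020 -> 1.270)

delta_e2000(lab_color(53, 46, 25), lab_color(90, -0.3, 21))
#> [1] 40.05425   # far beyond a visually obvious difference
```

A noiseless sigmoid fit recovers its parameters and derived statistics
exactly:

```r
fit_sigmoid(0:9, sigmoid_value(c(c0 = 29, cmax = 2172, k = 1.6), 0:9))
#> Sigmoidal accumulation fit: c(t) = cmax / (1 + (cmax-c0)/c0 * exp(-k t))
#>   c0 = 29 uM, cmax = 2172 uM, k = 1.6 /day
#>   inflection t* = 2.689 days, induction t_ind = 1.439 days
#>   RSS = 5.271e-26 on 10 observations
```

See `vignette("pigment-oxidation-kinetics")` (source under `vignettes/`)
for the models, assumptions, numerical choices and known limitations.

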