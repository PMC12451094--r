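---
title: "Models and methods: pigment degradation, lipid oxidation kinetics, and spectral colorimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigmentox)
```

# Scope

`pigmentox` quantifies two coupled processes in pigmented oil-in-water
emulsions during storage: the first-order degradation of anthocyanin
pigments and the sigmoidal accumulation of lipid oxidation products
(lipid hydroperoxides and the volatile aldehydes propanal and hexanal).
Around these two kinetic models it provides the supporting operations a
storage study needs: linear external calibration with inverse prediction,
absorbance-spectrum colorimetry (turbidity correction, peak location,
CIELAB conversion, CIEDE2000 colour differences), a seeded synthetic-data
generator with the replicate structure of a storage experiment, and
one-way ANOVA with Tukey compact letters for condition comparisons.

# Kinetic models

## First-order pigment decay

Anthocyanin concentration over storage time is modelled as
$$C(t) = C_0 e^{-kt},$$
with $C_0$ in µM, $k$ in day$^{-1}$, $t$ in days, and the half-life
$t_{1/2} = \ln 2 / k$. `fit_decay()` estimates $(C_0, k)$ by nonlinear
least squares *on the original concentration scale*, not by a log-linear
regression. The reason is practical: stored samples routinely decay to
concentrations indistinguishable from zero, and zeros are inadmissible on
the log scale. The log-linear regression over the strictly positive
observations is still used — but only to produce starting values.

Assumptions: additive, homoscedastic measurement error on the
concentration scale; a single first-order pathway (no induction in the
decay); non-negative concentrations.

Degenerate inputs are handled explicitly. An all-zero series is an error
(`"degenerate series"`): there is no amplitude to fit. A series with no
detectable decay is fitted at the boundary $k = 0$; the estimate is then
pinned to exactly zero (the boundary optimum $C_0 = \bar y$ is compared
directly against the interior optimum, because a Levenberg–Marquardt run
can stall at a tiny interior $k$ where the objective surface is flat),
$t_{1/2}$ is reported as `Inf`, and a warning flags the pin.

## Sigmoidal oxidation kinetics

Oxidation product concentrations follow the logistic form
$$c(t) = \frac{c_{\max}}{1 + \frac{c_{\max} - c_0}{c_0}\, e^{-kt}},$$
which starts at $c_0$, passes through an inflection, and saturates at
$c_{\max}$. Two derived statistics summarise a fitted curve:

* the **inflection point** at $t^\* = \ln\!\big((c_{\max}-c_0)/c_0\big)/k$,
  where the concentration is exactly $c_{\max}/2$ and the oxidation rate
  peaks at $k\,c_{\max}/4$;
* the **induction time** $t_{\mathrm{ind}} = t^\* - 2/k$, the intersection
  of the tangent at the inflection point with the time axis. When this
  intercept is at or below zero — series that start at a concentration
  already high relative to their plateau — no induction phase exists, and
  the statistic is reported as absent (an em dash in tables, `NA` in
  code). The boundary case $c_{\max}/c_0 = e^2 + 1$, where the tangent
  passes exactly through the origin, is classified as absent.

Both statistics are closed forms, and the test suite verifies them
against a purely numeric construction (Richardson-extrapolated second
differences, sign-change root finding, numeric tangent) at 1e-9 relative
accuracy over 1,000 random admissible parameter triples.

## Fitting strategy and numerical choices

`fit_sigmoid()` uses bounded Levenberg–Marquardt (via `minpack.lm`) with
multi-start over the rate constant, $k_0 \in \{0.05, 0.2, 0.8, 3.2,
12.8\}$ day$^{-1}$. The logistic's residual surface has long flat valleys
trading $k$ against $c_0$; a single start from a data-derived guess can
settle in the wrong valley, whereas the log-spaced ladder of starts
brackets any storage-relevant time scale (half a day to months). The
lowest residual sum of squares wins; ties at relative 1e-10 go to the
smallest $k$ (the slowest kinetics consistent with the data — the
conservative reading).

Bounds keep the parameters physically interpretable: $c_0$ in
$(10^{-6}\,\mu M,\ 2\times$ the smallest positive observation$]$ (the
lower bound keeps $(c_{\max}-c_0)/c_0$ finite), $c_{\max}$ in $[0.8, 3]
\times$ the largest observation, $k > 0$. Convergence uses tolerance
1e-12 on the relative reduction of the RSS.

A *flat* series — dynamic range below twice the noise floor, estimated
from successive differences as $\mathrm{sd}(\Delta y)/\sqrt2$ — carries no
kinetic information; it is returned with `converged = FALSE` and no
derived statistics rather than as a spuriously precise fit.

## Replicate aggregation and the Jensen gap

Experiments are replicated (independent emulsion preparations, each
measured more than once), and parameters are reported as mean ± SD across
replicate fits — each replicate is fitted on its own, then averaged
(`aggregate_replicates()`); pooled fitting remains available by
concatenating series before fitting. The per-replicate convention has a
visible numerical consequence: the mean of per-replicate half-lives is
*not* $\ln 2$ over the mean rate constant, because $1/k$ is convex.
With $k$-values $\{1, 2\}$, $\overline{t_{1/2}} = 0.520$ days while
$\ln 2/\bar k = 0.462$ days. Published parameter tables in this field
show exactly this gap, which is why the summary carries both numbers
(`t_half_mean` and `t_half_from_mean_k`) and why induction times are
averaged only over the replicates in which an induction phase exists
(with the count, `n_ind`, reported alongside).

# Colorimetry

## Turbidity correction and band arithmetic

Clarified emulsion extracts retain residual scattering. Since the pigment
does not absorb at 750 nm, the absorbance there measures that baseline,
and the quantification signal is `A(peak) − A(750)`
(`turbidity_correct()`, default peak 522 nm — the pigment maximum at
pH 2). The correction applies to the scalar quantification channel only,
not to the full-spectrum CIELAB pipeline, which operates on the measured
spectra as recorded. A negative corrected absorbance is returned, with a
warning, as a scattering artifact rather than silently clipped.

`lambda_max()` refines the grid argmax by a three-point parabolic fit,
with exact ties broken towards the shorter wavelength, and
`spectral_shift()` classifies the band movement between two conditions as
bathochromic (towards red), hypsochromic (towards blue) or none, together
with the relative intensity change at the respective maxima. The
denominator convention uses the *larger* of the two peak absorbances, so
a band growing from 1.0 to 1.25 is a +20% hyperchromic shift and the
reverse a −20% hypochromic one. (Under either convention a change from
0.51 to 1.0 is 49%, not 51%; the generator uses the measured absorbances,
so that pH 4 case reports ≈49%.)

## Absorbance to CIELAB

`spectrum_to_lab()` treats the sample as a transmitting medium,
$T(\lambda) = 10^{-A(\lambda)}$, and integrates rectangular sums of
$T \cdot S_C \cdot \bar x,\bar y,\bar z$ on a 5-nm grid over 380–780 nm
(input spectra are linearly interpolated onto the grid; coverage gaps
over 10 nm at either end are an error, smaller end gaps are filled by
edge extension). Normalisation is by $k_n = 100 / \sum S_C \bar y$, so a
perfectly transparent sample lands on the white point exactly. XYZ maps
to CIELAB through the standard piecewise cube-root with
$\varepsilon = 216/24389$ and $\kappa = 24389/27$. Viewing conditions are
fixed at illuminant C with the 1931 2° observer — the stated conditions
for this application — and carried on every `lab_color` so mismatched
comparisons fail loudly.

The CIE constants are built into `cie_tables()`: the colour-matching
functions as the published multi-lobe piecewise-Gaussian analytic fit
(Wyman, Sloan & Shirley 2013), the illuminant C spectral power
distribution as a 10-nm table interpolated to the working grid. The two
are mutually consistent: integrating them reproduces the illuminant C
chromaticity (0.31006, 0.31616) to within 4e-4, which the suite asserts.
A 5-nm rectangular rule is standard practice; the suite cross-checks the
whole pipeline against an independent 1-nm trapezoidal integrator.

An achromatic colour has no defined hue angle; `lab_color()` reports
`h = 0` with `hue_undefined = TRUE` rather than `NaN`.

## CIEDE2000

`delta_e2000()` implements the full CIEDE2000 formula — G chroma
rescaling, the $S_L, S_C, S_H$ weighting functions, the mean-hue
averaging rules, and the $R_T$ blue-region rotation term — with
$k_L = k_C = k_H = 1$. It is validated against published verification
pairs (including the hue-discontinuity cases) at 1e-4 and against an
independent implementation (`farver`) on 200 random colour pairs.

# Calibration and conversions

`fit_calibration()` is ordinary least squares of signal on concentration
(intercept included by default; a through-origin option exists because
instrument software sometimes forces it). The calibrated concentration
range is stored, and `invert_calibration()` flags any inverse prediction
outside it — including negative concentrations from signals below the
intercept — instead of refusing: the flagged value is often the right
input for a detection-limit decision. Predict and invert are mutual
inverses to 1e-12 on the calibrated range.

The unit conversions are linear and homogeneous:
`mass_fraction_to_molarity()` (percent w/w → mM; 0.1% SDS at
M = 288.38 g/mol is 3.47 mM) and `dilute_component()` (stock mM at a
g/L dose → µM in the final system; 0.79 mM iron dosed at 0.73 g/L is
0.58 µM). Both assume a stated density, default 1 g/mL — the reported
worked arithmetic closes only under that assumption.

# The synthetic-data generator

The generator exists so every stage is testable without the original lab
data, and its defaults encode the study conditions rather than being
tuning knobs:

* **Replicate structure**: 2 independent emulsion preparations × 2
  measurements each, on the storage grid 0, 1, 3, 5, 7, 10, 14, 17, 21
  days at 35 °C (the exact sampling days are not published; this is a
  plausible 21-day grid and the schema accepts any other).
* **Preparation effect**: the rate constant of each preparation is
  perturbed by a mean-one lognormal random effect with CV 10%, so that
  replicate scatter and ANOVA exercises are non-degenerate.
* **Measurement noise**: additive Gaussian, truncated at zero, default
  SD 5% of the curve's dynamic range.
* **True parameters** (`kinetic_presets()`): decay constants 1.44, 0.30,
  0.06, 0.09 day$^{-1}$ for pH 2, 3, 4, 6; sigmoid rate constants per
  analyte, pH and extract dose from the reported fits; day-0
  concentrations from the reported starting levels (e.g. hydroperoxides
  67/29/21/12 µM at pH 2/3/4/6). The pigment $C_0 = 24$ µM follows from
  the extract dose (0.73 g/L) and its anthocyanin content (order 1.3%
  w/w over ≈449 g/mol, ≈20 µM as cyanidin-3-glucoside equivalents).
  Plateau concentrations not published (both pH 2 hydroperoxide rows,
  the with-extract rows at pH 4/6) are fixed at plausible values
  consistent with the described plateau behaviour; they are generator
  conditions, not reproductions.

Synthetic spectra are single Gaussian bands on a 1-nm grid: centre
interpolating 522 → 546 nm over pH 2 → 6 (through 524 and 528), peak
absorbance falling 1.0 → 0.41, width growing with pH (40 nm + 4 nm per
pH unit, mirroring the broader measured bands at high pH), a flat 0.02
scattering baseline, amplitude decaying with storage day at the
pH-specific pigment rate, and photometric noise of SD 1e-4 absorbance
units (instrument-level; the band is flat near its maximum, so peak
location only carries sub-nanometre meaning at low noise). The
surfactant variant applies the measured adjustments (+8/+6/+2 nm and
hyperchromic at pH 2–4; −6 nm at pH 6).

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: mechanistic coupling between pigment decay
and oxidation (the two processes are simulated independently, whereas in
real emulsions radical scavenging links them), non-Gaussian or
heteroscedastic instrument error, drift between measurement sessions,
band asymmetry and multi-component spectra, and any matrix effect on the
calibration curves.

# Statistics and reporting

`anova_tukey()` wraps one-way `aov()` + `TukeyHSD()` at α = 0.05 and
condenses the pairwise decisions into a compact-letter display by the
greedy insert-and-absorb algorithm (start with one letter containing all
groups; for each significant pair, split every letter containing both;
absorb subset letters), with groups ordered by descending mean so the
highest mean always carries "a". The partition is deterministic and
stable under group relabelling. Zero residual variance is handled
outside the F machinery: equal-mean pairs are declared not different,
unequal-mean pairs different. Letters in the pipeline compare conditions
within each analyte on per-replicate fitted rate constants — comparing
fitted parameters, not raw curves, matches how such tables are reported.

`run_pipeline()` chains generation (or CSV input), per-replicate
fitting, aggregation, letters, CIELAB/CIEDE2000 colour tables (day pair
(0, 7) by default, configurable) and the spectral-shift table, writing
CSVs plus a JSON run log. Identical config and seed give byte-identical
numeric cells; every stage fails fast with the stage name on missing
inputs.

# Problem sizes

The suite and the acceptance script are sized for interactive runs: the
inflection/tangent oracle sweeps 1,000 random parameter triples; decay
recovery uses 200 seeded replicate experiments (and 40 in the unit
test); CIEDE2000 is cross-checked on 200 random pairs; the pipeline
tests run five presets. The acceptance script averages recovered
parameters over 10 independent simulated experiments per condition and
spectral shifts over 8 replicate spectrum pairs — the simulated analogue
of reporting means over duplicate measurements.

# Known limitations

* The decay and sigmoid fits assume homoscedastic Gaussian error;
  weighted fitting is not implemented.
* `c0` in the sigmoid is weakly identified when the induction phase is
  not sampled; its recovery tolerance is accordingly loose, while
  $c_{\max}$ and $k$ are tight.
* Alternative sigmoid families (Gompertz, Richards) and mechanistic
  radical-chain models are out of scope, as are other colour-difference
  formulas (CIE76, CMC, CIE94).
* The spectro-to-tristimulus bandpass correction applied by specific
  instrument firmware is unknown; plain rectangular integration is used.
* Compact letters are computed per analyte across conditions; per-day
  letterings would require the raw per-day values rather than fitted
  parameters.
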