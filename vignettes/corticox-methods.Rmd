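---
title: "Methods: models, estimators and numerical choices in corticox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and numerical choices in corticox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticox)
```

corticox analyzes two optical modalities that are acquired together on
one instrument: laser speckle contrast imaging (LSCI) of cortical blood
flow, and phosphorescence-lifetime oximetry of absolute oxygen tension
through a digital micromirror device (DMD) that confines excitation to
arbitrary regions. This vignette documents the models, the estimator
choices where the design was genuinely open, the synthetic-data
generators, and the numerical details a maintainer would need.

## 1. Speckle contrast and the single-exposure flow model

### The statistic

Speckle contrast is the local ratio `K = sigma_s / <I>` computed in a
square sliding window (default 7×7 pixels) centered at every pixel of a
raw frame. The implementation uses box sums of `I` and `I^2` over an
integral image; the variance is mean-of-squares minus squared-mean with
negative round-off clamped to zero before the square root, and the
standard deviation uses the population convention (divide by `N = 49`),
the form that box-filter pipelines compute. Pixels whose window leaves
the frame are flagged invalid, not padded: padded statistics would bias
`K` at the border. A window mean of zero flags the pixel invalid rather
than erroring, so a dark corner cannot abort a whole map.

### Small-window bias and its correction

The windowed estimator is biased low. For fully developed speckle the
time-integrated intensity is gamma-distributed with shape `1/K^2`, and a
delta-method expansion of `sigma_hat / I_bar` for `N` independent gamma
samples gives a first-order relative bias

    b(K) = -(3/4) (1 + K^2) / N,

about −2.4 % for `N = 49` at `K = 0.75` (our Monte-Carlo check measured
−2.31 %). That would be tolerable if contrast were the endpoint, but the
flow model inversion amplifies relative contrast errors by
`dln(tau_c)/dln(K)` ≈ 4.2 at `x = 1` and ≈ 7.1 at `x = 0.5`, turning a
2.4 % contrast bias into a ~10 % correlation-time bias — far outside the
3 % recovery this package promises. `compute_contrast()` therefore
applies the plug-in correction `K / (1 − 0.75 (1 + K^2)/N)` by default
(`bias_correct = FALSE` restores the raw ratio; the naive-oracle
equivalence tests run on the raw path, since they target the box-filter
arithmetic, not the estimator). The correction assumes the same gamma
statistics the model itself assumes; on real data with correlated
neighboring pixels the effective `N` is smaller and a residual bias of a
fraction of a percent should be expected.

### The exposure model and its inversion

With `x = T / tau_c`,

    K(T, tau_c) = sqrt( beta * (exp(-2x) - 1 + 2x) / (2 x^2) ),

`beta = 1` by default (an instrumentation property, assumed constant and
not estimated in software; overridable in `speckle_params()`). The
bracketed numerator suffers catastrophic cancellation as `x -> 0`: the
implementation uses `expm1` in the direct branch and switches below
`x = 1e-3` to the series `1 - (2/3)x + (1/3)x^2 - (2/15)x^3 + (2/45)x^4`,
giving better than 1e-10 agreement across the switch.

`invert_contrast()` solves `K(tau_c) = K_obs` by bisection on
`log(tau_c)` over `[1e-9 T, 1e6 T]` — 80 halvings, vectorized over
pixels, relative tolerance far below the contracted 1e-10; forward/invert
round-trips are exact to < 1e-9 over six decades of `tau_c`. Contrast at
or above `sqrt(beta)` has no finite solution (flow indistinguishable from
zero): such pixels are flagged invalid, never clamped, so that
downstream ROI statistics are not dragged toward an arbitrary ceiling.

### Relative flow

Contrast images are averaged first (n = 45 by default, i.e. one flow
sample per 0.75 s at 60 fps, timestamped at the block center) and then
converted to `tau_c`; `rCBF = tau_c,initial / tau_c` against the first
acquisition. Per ROI, corticox reports the **ratio of ROI-median
`tau_c`**, a deliberate choice among three candidates:

* *mean of per-pixel ratios* inherits a convexity bias of order the
  squared per-pixel coefficient of variation of `tau_c` from its noisy
  denominator (~+4 % at 45-image averaging) — measured, not hypothetical;
* *ratio of ROI means* removes that term but keeps the convexity of the
  model inversion itself, which inflates mean `tau_c` by 0.8–10 %
  depending on `x`;
* *ratio of ROI medians* is immune to both (the inversion is monotone,
  so the median commutes with it up to the small asymmetry of the
  contrast noise); measured residual bias is below 0.5 % across
  `x` in [0.25, 1].

All three coincide for the degenerate cases (baseline against itself is
exactly 1; a uniform doubling of `tau_c` gives exactly 0.5).

## 2. Lifetime oximetry

Decays are averaged on equal time bases (`n_averaged` accumulates), the
first 2 μs after gate-off are discarded and the time axis re-zeroed
(`apply_instrument_offset()`) — for a pure exponential this changes only
the amplitude, by `exp(-offset/tau)`, never the lifetime. The trimmed
trace is fit as `I(t) = A + B exp(-t/tau)` by bounded nonlinear least
squares (`nls`, port algorithm), with `A0` from the mean of the last 10 %
of samples and `(B0, tau0)` from a log-linear fit of `signal − A0` over
the first half of the window; `tau` is bounded to `[0.5 μs, 1 ms]`. `A`
is fit free (a pre-pulse baseline is not always available). A fit counts
as converged only if the optimizer converged, `B > 0`, and the relative
standard error of `tau` is below 20 % — the instrument literature gives
no quality criterion, so this gate is a package choice; failed fits
yield missing timecourse samples rather than exceptions, keeping series
contiguous.

Lifetime converts to oxygen tension by Stern–Volmer kinetics,
`pO2 = (1/tau − 1/tau0)/kq` with `kq = 291.014 mmHg⁻¹s⁻¹` and
`tau0 = 47 μs` (the probe's unquenched lifetime at zero oxygen under
physiological conditions). Strictly, pure Stern–Volmer behavior is
asserted only for `tau < 16 μs`; the measured calibration curve above
that is not available in tabulated form, so the analytic branch is
applied across the full range **with a warning**, and a user-supplied
`(tau, pO2)` table (monotone Hyman-filtered cubic interpolation)
overrides it when available. Absolute pO2 in the physiological regime
therefore carries the uncertainty of that extrapolation. Negative
computed pO2 (`tau > tau0`, possible under noise) is clamped to zero and
flagged, not erred.

## 3. Targeting geometry

Coordinates are 0-based, `x = column`, `y = row`, points at pixel
centers, tile intervals half-open — the convention is stated because
nothing upstream states one. The camera-to-DMD affine is estimated from
≥ 3 control-point pairs by least squares (exact for 3 noncollinear
pairs; RMS residual reported beyond that). Masks are rasterized onto the
608×684 mirror array by inverse-map nearest-neighbor pullback: binary
masks stay binary, and no interpolation threshold has to be invented.
Mask content mapping outside the DMD is clipped with a logged
percentage rather than an error, because ROIs near the field edge are
legitimate. The DMD mirror pitch (7.6 μm) is metadata only; all optical
magnification lives in the affine map.

Schedules encode the pulse-gating and averaging budget: duty cycle
`pulse_width × rep_rate` (20 μs × 3 kHz = 6 %), per-pattern decay time
`decays_per_pattern / rep_rate`, and feasibility
`decay time ≤ 1/pattern_rate` (200 decays at 3 kHz in a 10-Hz slot:
66.7 ms ≤ 100 ms). The reference 12×8 tile grid over 1.2 × 1.0 mm yields
96 tiles of 0.0125 mm² and a 9.6-s scan at 10 Hz.

## 4. Wavelength penetration estimate

Transmittance through a surface vessel is pure Beer–Lambert,
`T = exp(−ln(10) C (SaO2·eps_HbO2 + (1−SaO2)·eps_Hb) L)` — deliberately
no scattering, which makes it the most conservative (largest) estimate
of transmission. Defaults: `C = 2.3 mM` hemoglobin tetramer,
`SaO2 = 0.95`, `L = 100 μm`. The bundled extinction values at 445 and
637 nm are linear interpolations of the standard tabulated hemoglobin
compendium on the tetramer basis. At 637 nm (flat Q-band tail) the
result, 96.6 %, is robust to the table choice. At 445 nm the extinction
sits on the steep red flank of the Soret band, where different standard
tables (and ±5 nm of wavelength) move the answer by multiples; the
bundled table gives 2.1 % transmitted, the same order as — but not equal
to — other tabulations. The qualitative conclusion is table-independent:
blue excitation is confined to the vessel (two orders of magnitude more
absorption than red). Users with a preferred table can override via
`read_extinction_csv()`.

## 5. Synthetic data: what it emulates, what it does not

`synth_speckle_stack()` draws each pixel of each frame independently
from a gamma distribution with shape `1/K*^2` and prescribed mean, where
`K*` is the model contrast of that pixel's true `tau_c` — so windowed
contrast converges to `K*` and the full analysis chain can be tested for
estimator bias. It does **not** simulate spatial speckle correlation
(real speckle grains span pixels, lowering the effective sample count
per window), photon shot noise, or camera read noise. A green recovery
test therefore establishes correctness of the estimator chain under the
model's own statistics, not robustness to real-sensor artifacts.

`synth_decay()` generates `A + B exp(-t/tau)` with `tau` from the
calibration and additive white Gaussian noise of standard deviation
`noise_sd / sqrt(n_averaged)` — noise after on-board averaging is
near-Gaussian by the CLT; PMT shot-noise statistics are out of scope.

`synth_stroke_session()` scripts a targeted-occlusion experiment: region
flow factors scale `tau_c` inversely (rCBF is the factor by
definition), pO2 setpoints drive decay generation, and an optional
spreading-depolarization transient applies a multiplicative dip
traveling across regions with configured lags (a scripted template —
the underlying physiology is not modeled). The default template has two
arterioles, a vein and two parenchyma regions (A1, A2, V1, P1, P2) with
baseline pO2 of 80/78/50/60/62 mmHg — arterial values near arterial
oxygen tension, venous and parenchymal lower, matching physiological
expectations — and one event halving flow in A1 at t = 120 s with pO2
dropping to 20 mmHg. The perturbed territory extends 3 px (half the
contrast window) beyond each measurement region, because an occlusion
affects the vessel and its surroundings; without that margin, windows
centered near the region edge would straddle the perturbation boundary
and mix flow statistics from both states.

Generators take explicit integer seeds, restore the caller's RNG state,
and are byte-deterministic for a fixed seed.

## 6. Tolerances and test scaling

* Box-filter contrast vs. the naive two-pass oracle: 1e-12 relative.
* Forward/invert round-trip: 1e-9 over `tau_c` in [1 μs, 0.1 s].
* Series/direct model agreement: 1e-10 on `x` in [1e-6, 1e-3].
* Regional `tau_c` recovery (45-image averaging, window 7): 3 % median.
* pO2 recovery at SNR 5 with 200-decay averaging: < 2 % median bias,
  > 95 % converged (decays sampled at 10 MHz in the test — the property
  concerns noise and averaging, not the digitizer rate — to keep 200
  fits inside the test budget).
* Occlusion-session rCBF: 0.5 / 1.0 ± 0.01, tested on 192×192-px
  regions so the tolerance sits at ≥ 3 standard errors of the ROI
  statistic; smaller regions would make the band a coin flip.

## 7. Known limitations

Single-exposure LSCI flow indices are relative by construction;
cross-session or cross-animal comparability (a multi-exposure extension)
is out of scope. Absolute pO2 above `tau = 16 μs` depends on an
extrapolated calibration unless a measured table is supplied. The TIFF
codec is intentionally minimal (uncompressed grayscale, strip-organized,
uint16/float32) — it reads what the instrument writes and what this
package writes, not arbitrary TIFF. Masks use plain-text PGM rather than
PNG so the package has zero image-library dependencies.
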