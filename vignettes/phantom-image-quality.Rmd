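---
title: "Phantom-based image quality for photon-counting CT angiography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based image quality for photon-counting CT angiography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctiq)
library(dplyr)
```

`ctiq` answers a concrete question in CT angiography of the lower legs:
which reconstruction kernel sharpness and which iterative-reconstruction
(QIR) strength best depict a small contrast-filled vessel and its wall?
The package provides a digital stand-in for the physical experiment that
question is usually answered with — a silicone tube filled with an iodine
dilution, immersed in water, scanned at several doses and reconstructed
with every kernel — together with the edge-profile analysis chain used to
score such images, and the nonparametric statistics used for the
accompanying reader studies.

This vignette explains the models, their assumptions, the tunable
parameters, and the design decisions taken where the underlying
measurement protocol left room for interpretation.

## Kernel model

A reconstruction kernel is characterised by two anchor frequencies: the
spatial frequencies at which its modulation transfer function (MTF) falls
to 50% and 10% of the zero-frequency value ($\rho_{50}$, $\rho_{10}$, in
Lp/cm). `kernel_table()` ships the ten quantitative kernels (sharpness
levels 36–76) with their anchors and the maximum edge slopes measured at
the reference condition.

Two anchor points do not fix a curve, so a two-parameter monotone family
is fitted through them:

$$\mathrm{MTF}(\rho) = \exp\!\left[-(\rho/a)^b\right],
\qquad b = \frac{\ln(\ln 10 / \ln 2)}{\ln(\rho_{10}/\rho_{50})},
\qquad a = \frac{\rho_{50}}{(\ln 2)^{1/b}}.$$

The closed form passes through both anchors exactly, is strictly
decreasing, and equals 1 at DC. The choice of family matters mostly in
the tails: between the anchors all reasonable monotone interpolants agree,
but the ringing of the implied point-spread function depends on how
abruptly the curve falls beyond $\rho_{10}$. One consequence is worth
knowing: the printed anchors make the sharpness-64 kernel nearly
rectangular ($\rho_{50} = 10.1$, $\rho_{10} = 11.2$, so $b \approx 11.6$),
and adjacent fitted curves can cross by a fraction of a percent near DC
and in the far tail. Mid-band (where resolution lives) the family is
ordered by sharpness.

`nyquist_frequency(voxel_mm)` returns $1/(2\Delta x)$; at the default
0.4 mm isotropic voxel this is 12.5 Lp/cm. Kernels whose $\rho_{10}$
exceeds this value cannot add sharpness on this grid — they only add
noise, which is the physical argument for a "plateau" of useful sharpness
levels.

### Noise model

The background noise SD is modelled as separable in kernel, QIR level and
dose:

$$\sigma(k, q, D) = \sigma_0(k)\; f_q \; \sqrt{3\,\mathrm{mGy}/D}$$

* $\sigma_0(k)$ is anchored at the three measured values (16, 38, 77 HU
  for sharpness 44, 60, 72 at QIR-3 and 3 mGy) and interpolated
  log-linearly in sharpness level between them (linearly extended
  outside; levels outside 36–76 are flagged as extrapolated).
* $f_q$ are the QIR ratios measured at the sharp kernel: $51/38$, $1$,
  $25/38$ for QIR-2/3/4. The measurement protocol reports ratios only at
  one kernel; transferring them to all kernels is the simplest model
  consistent with every printed value.
* The dose term is the quantum-noise inverse-square-root law.

## Phantom simulator

`rasterize_phantom()` renders the concentric lumen/wall/water geometry on
a 512×512 grid (204.8 mm field of view, tube centred). Pixels cut by a
material boundary are area-weighted by 8×8 supersampling, which keeps the
rendered wall mass within 0.5% of the analytic annulus area; pixels away
from boundaries take their material value exactly, so the far field is
water bit-for-bit.

Attenuation is linear in iodine concentration. The calibration constants
default to 500 HU for silicone and 52 HU·mL/mg for iodine at 55 keV.
These are package defaults, not measured facts: they were chosen so that
(a) the blurred wall amplitude of a saline-filled 2 mm tube reproduces the
measured 316/387/511 HU for the soft/medium/sharp kernels (the simulated
values are 317/387/527), and (b) the 9.25 mg I/mL dilution
(9.25 × 52 = 481 HU) is nearly iso-attenuating with the wall, which is
the regime in which the wall–lumen transition disappears from the slope
analysis. Both constants are arguments of `phantom_spec()`.

`apply_kernel()` multiplies the image spectrum by the radially symmetric
MTF (unit DC gain, so means are preserved). `add_noise()` draws a
stationary Gaussian field with power spectrum $\propto \rho \cdot
\mathrm{MTF}(\rho)^2$ — the standard model for ramp-filtered
reconstruction noise — and rescales it so its SD equals the noise model's
target. The measurement protocol reports only noise SDs, never a noise
power spectrum, so the SD is calibrated and the texture is the standard
model. Noise is seeded and bit-reproducible, and the global RNG state is
left untouched.

`simulate_slice()` composes the three steps and records provenance.
Setting `ctdi = Inf` yields the noise-free blurred phantom, which is
exactly independent of the QIR level — in this model QIR acts on noise
alone.

What the simulator deliberately does not emulate: projection-domain
physics (beam hardening, photon-counting bin weighting), the water
container walls and table, helical geometry, and any nonlinearity of the
vendor's iterative reconstruction. Passing tests therefore show that the
*analysis chain* behaves correctly on images with realistic first-order
blur and noise, not that the simulator reproduces every property of
scanner data.

## Edge-profile analysis

`analyze_image()` runs the measurement chain:

1. centred crop to 128×128; background noise = mean of the sample SDs in
   the two bottom-corner 44×44 water ROIs;
2. centred crop to 64×64; horizontal and vertical profiles = mean of the
   4 central rows/columns (an even band cannot centre on one pixel, so it
   straddles the midline);
3. amplitude = mean over the two profiles of (profile maximum − water
   background), the background taken from the outer 8 points of each
   profile end. In-phantom water is 0 HU, so this referencing is
   near-neutral; it matters for real images with offset backgrounds;
4. slope at each interior point = least-squares slope of the three
   neighbouring points, which at uniform spacing is the central
   difference $(y_{i+1}-y_{i-1})/2h$;
5. each of the eight nominal transitions (water↔wall and wall↔lumen,
   both sides, both profiles) is assigned the strongest local maximum of
   $|$slope$|$ within ±0.8 mm (two pixels) of its nominal radius, with
   each local maximum claimable only by its nearest nominal boundary, so
   a single merged peak is never counted twice. Ties go to the candidate
   closer to the nominal position.
6. the slope score (0–8) counts transitions that own a distinct local
   maximum above the visibility threshold; the mean slope maximum
   averages the four per-profile maxima and then the two profiles.

### The visibility threshold

A transition counts only if its slope maximum is "visible above the noise
level". This is formalised as $c \cdot \sigma_\mathrm{slope}$ with
$c = 2$ by default. $\sigma_\mathrm{slope}$ is *measured*, not derived:
reconstruction noise is spatially correlated, and the shaped spectrum
$\rho\,\mathrm{MTF}^2$ concentrates power exactly in the passband of the
slope operator, so white-noise error propagation
($\sigma/(2h\sqrt{w/2})$ for a $w$-pixel band) underestimates the slope
noise by roughly 40% at the sharp kernel. `estimate_slope_noise()`
therefore applies the identical band-average + three-point-slope chain to
the water background of the corner ROIs and takes the SD of the result;
on white noise this reproduces the closed form (which remains available
as a documented fallback). With the measured threshold, every simulated
9.25 mg I/mL acquisition at 3 mGy scores 4 — the iso-attenuation
signature — whereas the white-noise threshold lets noise spikes leak
through as spurious wall–lumen detections.

### A known disagreement at full contrast

At 37 mg I/mL the lumen sits near 1924 HU against a 500 HU wall: the
wall–lumen slope peak is roughly eight times stronger than the
water–wall peak one millimetre away. Under this MTF family the sharp
(sharpness-60) kernel leaves the water–wall maximum as a *shoulder* on
the stronger peak's tail — in the continuous profile the two maxima are
separated by a dip only ≈0.55 mm wide, which the 0.8 mm span of the
central difference at 0.4 mm sampling bridges. The simulated sharp-kernel
slope score at full contrast is therefore 4 at every dose, while the
published worked example reports 8 for a real acquisition of the same
nominal configuration. The margin is well under 1% of the peak slope;
which side of it a system lands on depends on details the model cannot
know (the vendor's true MTF beyond two anchors, sub-pixel tube
placement). Kernels of sharpness 64 and above resolve all eight
transitions robustly, and the sharp kernel itself does so at 18.5 mg
I/mL. We report the model's answer rather than forcing the example.

## Factorial sweep

`run_sweep()` executes `simulate_slice()` + `analyze_image()` over the
factorial design (kernels × QIR × dose × diameter × concentration ×
seeds) and returns a long tibble; `plateau_summary()` and `score_grid()`
reproduce the derived views (relative slope differences to a reference
kernel; per-dose score grids, median across seeds). The default
configuration is a desk-scale subsample (3 kernels × 3 QIR × 2 doses ×
2 diameters × 3 concentrations × 5 seeds); `full_grid = TRUE` selects
the complete 4500-cell design. The physical experiment acquires one scan
per cell; the simulator defaults to 5 seeds per cell and reports medians,
because single draws of the stochastic metrics carry unreported sampling
error. Cell results can be cached as per-cell CSVs and are skipped on
rerun; per-cell failures are recorded in an `error` column rather than
aborting the sweep.

## Reader-study statistics

`wilcoxon_paired()` runs two-sided paired signed-rank tests with
Bonferroni adjustment (`min(1, m·p)`). Zero differences are discarded
(the classical convention; the protocol does not state one). For ≤ 25
non-zero pairs the exact distribution is computed by a dynamic program
over doubled average ranks — ordinal data always produce tied
$|$differences$|$, and the textbook exact tables (and
`stats::wilcox.test`'s exact path) do not apply under ties. Larger
samples use the normal approximation with tie correction.

`krippendorff_alpha()` implements the coincidence-matrix agreement
coefficient $\alpha = 1 - D_o/D_e$ with the *ordinal* distance metric
$\delta^2_{ck} = (\sum_{g=c}^{k} n_g - (n_c+n_k)/2)^2$, matching the
Likert scale (the protocol names only the coefficient, not the metric).
Missing ratings are handled; units with fewer than two ratings are
ignored; data without variation yield an undefined $\alpha$ rather than a
misleading 1. `interpret_alpha()` maps $\alpha$ to the conventional
bands with cut points 0.2/0.4/0.6/0.8, half-open upward ("greater than
0.2 up to 0.4" is fair); negative values are "poor" since the published
bands start at 0.0.

`synth_likert()` generates a complete synthetic reader study (3 readers ×
20 patients × 9 reconstructions × 3 criteria × 2 anatomic levels) from a
latent-Gaussian ordinal model: latent = cell target median + per-reader
bias + residual noise, rounded and clipped to 1–5. The per-cell targets
ship as a packaged CSV of medians and interquartile ranges; the residual
SD grows with the target IQR width (`residual_sd + iqr_sd_slope · IQR`,
defaults 0.3 and 0.5 — chosen so that cells reported with wider spread
are noisier, while degenerate-IQR cells stay concentrated), and reader
biases are drawn once per reader (SD 0.2, emulating mild systematic
leniency differences). With zero noise and zero bias every rating equals
its cell's target median exactly. The generator is a synthetic stand-in:
the real reader data are not deposited, so the clinical p-values and
agreement coefficients are not reproducible and are not claimed by any
test; what the tests do show is that the statistics recover designed
properties (agreement rising to 1 as residual noise vanishes, exact
agreement with independent oracles).

## Numerical choices and problem sizes

* FFT-based filtering on the native 512×512 grid; the rasterize → blur →
  add-noise composition is the specified acquisition model.
* Noise fields are rescaled by their own sample SD, so the realised
  background SD matches the model target up to ROI sampling error
  (±1–2 HU at a 44×44 ROI).
* Supersampling factor 8 per axis bounds the rasterisation area error
  below 0.5%.
* Transition search window ±0.8 mm: wide enough to catch blur-shifted
  maxima at the softest kernel, narrow enough to separate the two wall
  boundaries for diameters ≥ 2 mm.
* Test and example workloads use reduced designs (e.g. 256-pixel grids
  for noise-law checks, 3 seeds per cell for score medians, 45–170
  slices per acceptance computation) — sizes at which the reported
  medians are stable across reruns with different master seeds.

## Limitations

* The MTF beyond the two printed anchors is an assumption; conclusions
  that hinge on sub-percent slope differences near the resolution limit
  (the full-contrast sharp-kernel case above) are model-dependent.
* QIR is a pure noise-scale factor; real iterative reconstruction is
  nonlinear and mildly affects edges.
* The noise texture is the standard ramp-filtered model calibrated to SD
  only.
* The Likert generator matches per-cell medians and spread, not
  inter-criterion correlations within a patient.
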