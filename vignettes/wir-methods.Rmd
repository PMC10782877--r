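---
title: "Wavelength-independent estimation of tissue optical properties: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength-independent estimation of tissue optical properties: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drswir)
```

This vignette is the package's own account of its science: the measurement
model, the synthetic-data generator and what it does and does not emulate,
the six use-error corruptions, the 35 features, the regression models, and
every numerical choice a maintainer might want to revisit. It states no
empirical result that the test-suite or `scripts/acceptance.R` does not
itself compute.

## 1. The measurement and its data model

A fiber-optic probe illuminates tissue with a white LED and collects the
diffusely reflected light at a source–detector separation (SDS) of 750 μm
(probe 1) or 650 μm (probe 2). A grating disperses the collected light
across the pixel columns of an 8-bit RGB camera, so the raw datum is an
M × N × 3 image whose columns map linearly to wavelength on the 450–630 nm
band:

$$\lambda(j) = 450 + j\,\frac{630-450}{N-1}, \qquad j = 0,\dots,N-1 .$$

The default N = 585 gives ≈ 0.308 nm per pixel, consistent with the
device-level observation that 12 pixels span about 3.7 nm. Only this ratio
is physically meaningful; the linear map itself is the package's choice.

Preprocessing of a measured image (`preprocess_image()`) proceeds in the
fixed order

1. **threshold** — channel values strictly below 10 DN are background and
   set to 0, independently per channel (so the pixel (0, 20, 9) becomes
   (0, 20, 0));
2. **exposure normalisation** — $I_{norm} = I_{raw}/(T_i \cdot ISO)$, which
   makes captures at $(c\,T_i,\ ISO/c)$ identical;
3. **row collapse** — the spectral intensity at column $j$ is the sum of
   the normalised intensities over the M rows, per channel; the gray
   spectrum is the elementwise sum R + G + B, an identity preserved by
   every later (linear) step;
4. **moving average** — a six-column centred window (three columns left,
   two right of the index, edges reflected);
5. **reflectance standard** — measured spectra are *divided* by the
   standard's spectrum to remove the instrument response; simulated spectra
   are instead *multiplied* by it (section 2), so that the instrument
   response lives inside the training distribution and a clinical user
   need not carry a calibration puck. Both modes are exposed and neither is
   silently assumed.

Acquisition metadata travel in a JSON sidecar next to the PNG (no EXIF
parsing), keeping the image format independent of the camera vendor.

## 2. The synthetic-data generator

No public dataset of this device class exists, so the package generates its
own labelled spectra. The generator's defaults *are* the study conditions;
they were fixed while designing the generator and are not tuned per
experiment.

### 2.1 Forward reflectance model

At sub-millimetre SDS the detected photons have travelled short, weakly
dispersed paths. The collected reflectance then factorises into a
scattering amplitude and a Beer–Lambert absorption term along a mean
partial pathlength:

$$R(\lambda) \;=\; k\; \mu_s'(\lambda)^{1.5}\,
   \exp\!\big(-\mu_a(\lambda)\, L(\mu_s')\big),
 \qquad L = 0.22\,\Big(\frac{8}{\mu_s'}\Big)^{0.35}\ \text{cm}.$$

This closed form deliberately mirrors the structure of Monte-Carlo
reflectance at these distances: scattering sets the overall intensity
scale, absorption carves the spectral *shape*. We first implemented the
extrapolated-boundary diffusion dipole at the probe SDS and rejected it:
at 750 μm the detector sits inside the first dipole's near field
(SDS < 1/μt′), where the growth of the $1/r^2$ prefactor as the source
depth shrinks nearly cancels the absorption exponential, leaving μa almost
unobservable — an artifact of evaluating the diffusion Green's function
where diffusion theory does not hold, not a property of the physics. The
Beer–Lambert form is monotone decreasing in μa at every wavelength and
monotone increasing in μs′, both of which the test-suite asserts.

The model deliberately omits: photon-transport simulation, layered or
heterogeneous media, fluorescence, probe-pressure effects, and any
Mie computation from sphere size and index. The exponent 1.5 and the
pathlength constants are fixed package defaults of realistic magnitude for
this SDS range, not fitted quantities. If absorption reaches reduced
scattering anywhere on the band the weak-absorption premise is violated;
the forward function warns and proceeds.

### 2.2 Chromophore and instrument shapes

Scalar labels scale fixed spectral shapes, both normalised to band mean 1
on the evaluation grid so that **the label equals the band-average
coefficient exactly**:

* **Absorption** — an oxyhemoglobin-like extinction curve (the phantoms the
  device was built for are hemoglobin + polystyrene suspensions): a
  log-scale spline through 21 anchor values reproducing the Soret tail at
  450 nm, the Q bands at 542/576 nm, and near-transparency beyond 600 nm.
  The anchors are approximate published-order values, packaged as a
  synthetic curve.
* **Scattering** — a Mie-like power law $(\lambda/540)^{-0.37}$, the
  typical slope of 1 μm polystyrene spheres in the visible.
* **Instrument response** (`default_standard()`) — a cool-white-LED-shaped
  curve: narrow blue peak at 455 nm, the characteristic "cyan gap" near
  480 nm, a broad phosphor hump at 560 nm declining gradually into the
  red, soft roll-on at the blue band edge, strictly positive everywhere.
  The cyan gap matters: it places the spectrum's quarter-maximum crossings
  on flanks that move with absorption, which keeps the spectrum-length
  features informative (section 4).

### 2.3 The label grid

The default dataset is the Cartesian 40 × 38 grid of equally spaced labels
over μa ∈ [0.44, 2.45] cm⁻¹ and μs′ ∈ [6.53, 9.58] cm⁻¹ — 1520 spectra
whose label extremes hit the range endpoints exactly, one synthetic
"titration" group per μa level. An alternative design was considered —
1520 uniform label pairs quantised to steps of 0.007 and 0.008 cm⁻¹
(≈ 286 and ≈ 382 distinct levels), trading the regular grid for
quasi-continuous label coverage; the two designs give the estimator
comparable accuracy, and the grid was kept because the inversion
experiments and the coverage invariants require it.

### 2.4 Grayscale → RGB decomposition

Simulated spectra are grayscale; channel spectra are derived by a
wavelength → RGB map. The package uses a documented piecewise-linear
visible-spectrum approximation (blue falls 490–510 nm, red rises
510–580 nm, green falls 580–620 nm; pure red beyond 620 nm) with the usual
band-edge intensity falloff disabled so the triple sum is nonzero on the
whole working band. Per column the triple is converted to fractions
(channel / sum, summing to one) and the gray intensity is split
proportionally, so R + G + B reconstructs gray exactly — a conservation
identity the tests assert at 10⁻¹² relative tolerance, together with
linearity of the split. The worked fraction example (0, 255, 146) →
(0, 0.64, 0.36) is reproduced exactly. The third-party calculator this
emulates used an unpublished modification, so its exact triples are *not*
reproduced; only the fraction arithmetic is contractual.

## 3. The use-error corruption suite

Six corruptions emulate realistic mishandling; magnitudes are the study
conditions and live in `drs_error_config()`:

| corruption | default | definition |
|---|---|---|
| noise | SNR 35:1 (45:1 compounded) | zero-mean Gaussian, σ = RMS(signal)/SNR |
| shift | −4.8 nm | intensities interpolated onto the shifted axis; grid labels unchanged (the miscalibration is silent); vacated columns 0 |
| compression | 1 nm per tail | affine squeeze of [λmin, λmax] onto [λmin+1, λmax−1]; margins clamp the edge values |
| rotation | up to 5 % | linear ramp (1+a) → (1−a), left tail up, right tail down, a ~ U(0, 0.05) per spectrum; midpoint unchanged |
| scaling | up to 5 % | one factor ~ U(1, 1.05) per spectrum |

Choices worth recording:

* **SNR is a linear RMS amplitude ratio.** The dB convention of common
  noise-injection utilities would give quieter noise; the ratio notation
  "35:1" is taken literally. Configurable.
* **Scaling is one-sided (up)** and **rotation has a fixed orientation**
  (left up, right down) with random magnitude. A warming light source
  drifts in one direction, so the one-sided forms are the physically
  representative conditions; symmetric variants would double the
  corruption variance.
* **Compounding order** is scale → rotate → shift → compress → noise:
  detection noise enters after all optical and calibration distortions.
  The order is fixed, documented and tested, not configurable.
* Corruptions act on the gray (standard-multiplied) spectrum; channels are
  re-derived through the fixed fractions, which keeps gray = R + G + B
  exact under every corruption including noise.
* Every corruption preserves record count, labels, grid length and group
  ids; zero-magnitude configurations are exact no-ops; everything is
  bit-reproducible given a seed.

The **augmentation suite** applies 14 corruption rows (row 1 = untouched,
rows 2–6 single errors, rows 7–14 compounded combinations, row 11 all
five at the compounded SNR) to the 1520-record base set:
14 × 1520 = 21,280 training records. The **evaluation suite**
(`condition_suite()`) is the seven conditions: perfect, noise, shifted,
scaled, compressed, rotated, all-compounded.

## 4. The 35 wavelength-independent features

Per record, from the four channel spectra (R, G, B, gray):

* max, mean, sd of intensity (12);
* max, min, mean, sd of the per-column first differences (16) — slopes are
  per *pixel column*, not per nm, so they never reference the axis;
* spectrum length 1: number of columns strictly above 0.25 × max of the
  gray spectrum (1);
* spectrum length 2: pixel distance between the gray spectrum's absolute
  maximum and its highest *other local maximum* (strict neighbours,
  leftmost tie-break; 0 if no second local maximum) (1);
* skewness (biased m₃/m₂^1.5) per channel (4);
* the categorical probe id (1).

The layout is frozen: lengths are computed on the gray spectrum only and
skewness per channel, which is the unique assignment under which the
itemised families sum to exactly 35 entries.

Feature extraction clamps intensities at zero first (preprocessed spectra
are nonnegative by construction; corrupted spectra can carry unphysical
negative noise excursions in their dim tails) and then applies the
pipeline's six-column moving average to each channel before any statistic
is computed. Computing statistics on the smoothed spectra is the package's
uniform reading of the preprocessing chain; the window is the chain's
window. Degenerate all-zero channels yield zero statistics with a warning
(zero-variance skewness is defined as 0).

Invariances the tests assert: systematic scaling changes no
scale-invariant feature (lengths, skewnesses, probe — exactly for the
integer features, to 10⁻¹² for skewness); a 4.8 nm shift of a smooth
in-band spectrum changes intensity statistics by < 1 % and spectrum
length 1 by ≤ 2 columns; extraction is deterministic and its order frozen.

## 5. Models

### 5.1 The WIR estimator

`wir()` fits one gradient-boosted tree ensemble per target with 200
estimators, maximum depth 5, minimum 3 samples per leaf, learning rate
0.1, exact greedy splits, single-threaded, random state 0 — the reference
gradient-boosting configuration, reproducible bit for bit. Two package
design choices:

* **Log-scale targets.** Accuracy is assessed as relative RMSE; fitting
  log μa and log μs′ matches the squared-error loss to that metric
  (predictions are exponentiated back).
* **Range clamping.** Tree ensembles do not extrapolate; predictions are
  clamped to the training label range, which also makes that contract
  explicit.

Gain-based feature importances are normalised over all 35 features and
exposed via `feature_importances()`, `summary()` and `plot()`. Models
persist as a versioned bundle (two boosters plus a JSON manifest carrying
the frozen feature order); loading or predicting with a mismatched layout
is refused.

### 5.2 The spectral-matching inversion (MCI baseline)

`mci_invert()` minimises the sum of squared wavelength-by-wavelength
differences between the measured spectrum and the forward model, over
μa ∈ [0.3, 3.0], μs′ ∈ [5.5, 10.5] (slightly wider than the generation
ranges): a coarse precomputed candidate library (200 × 200 by default;
the coarse match over a whole dataset is a single blocked matrix product)
followed by Nelder–Mead refinement at 10⁻¹⁰ relative tolerance.
Non-convergence is flagged and the best-found values returned. On
noiseless in-grid spectra the inversion recovers the generating labels to
well below 0.01 % — the self-consistency of any forward/inverse pair —
and the tests verify agreement with an independent brute-force dense-grid
argmin on a toy grid.

### 5.3 The dense NN baseline

A two-hidden-layer (25 + 25 units, ReLU) regression network per target,
trained with full-batch Adam on standardised inputs, mean-squared-error
loss, early stopping on a 10 % validation split (patience 25, at most 500
epochs), fixed seed. It accepts either the 35 features or the raw
concatenated spectra (gray, R, G, B → length 4N). It is deliberately
minimal baseline plumbing: its contract is finiteness, reproducibility and
the stated architecture, not accuracy.

## 6. Evaluation protocols and problem sizes

* `kfold_cv()` — disjoint random folds covering the data; pooled
  predictions; percent RMSE per target,
  $100\sqrt{\text{mean}(((\hat y - y)/y)^2)}$ (the alternative
  RMSE/mean(y) normalisation is available).
* `leave_one_group_out()` — one evaluation per group (titration), training
  on all other groups plus optional augmentation records, which never
  enter a test fold; the summary is the arithmetic mean of per-group
  errors.
* `robustness_experiment()` — the full robustness experiment: every requested
  model on each of the seven conditions, with informational (never
  asserted) prediction wall times.

The test-suite runs its unit and property tests on reduced grids (typically
5 × 5 to 6 × 5 labels, 80–146 wavelength columns) and its study-scale
checks on the full 1520-spectrum, 585-column dataset: inversion
self-consistency on all 1520 perfect spectra, fivefold CV of the WIR on
all seven conditions, the 21,280-record augmentation count, and the
order-of-magnitude robustness gap between MCI and WIR on the all-errors
condition. `scripts/acceptance.R` recomputes the headline quantities from
scratch at the same sizes.

## 7. Numerical choices, degenerate inputs, reproducibility

* Moving average: even windows centre as 3 left / 2 right; edges reflect
  including the edge sample; window 1 is the identity.
* Shift/compression use linear interpolation; piecewise-linear spectra
  round-trip a shift exactly, smooth spectra to within the standard
  $h^2 f''$ interpolation bound (both tested).
* Ties in peak finding break leftmost; a spectrum with no second local
  maximum has spectrum length 2 equal to 0; an all-zero spectrum has
  length 1 equal to 0.
* The renderer scales the brightest pixel to `peak_dn` (250 by default),
  quantises to 8 bits and clips at 255 with a warning; a rendered spectrum
  survives the full preprocessing round trip with per-column relative
  error within the quantisation bound 2/`peak_dn` on columns above
  half-maximum (tested).
* All randomness flows from one master seed through
  `derive_seed(seed, stage)` (a deterministic 31-bit string hash), so a
  single integer reproduces the entire pipeline bit for bit; pipeline
  artifacts carry the MD5 of the effective configuration.
* Library scans are blocked (8000 candidates at a time) to bound memory.

## 8. What passing tests do and do not show

The generator emulates the *structure* of the study: label ranges and
count, instrument-response imprinting, the six corruptions at their stated
magnitudes, grouped records. It does not emulate photon transport, camera
demosaicing, probe-to-tissue contact variability, day-to-day hardware
drift, or chromophores beyond the single hemoglobin-like absorber. Results
on synthetic data therefore demonstrate the estimator's robustness to the
*modelled* use-errors, not clinical performance: in particular, the
absolute error levels depend on the closed-form forward model and would
differ under a transport-accurate simulator or on measured phantom data,
where day-effects and uncorrected instrument drift dominate. The
leave-one-group-out protocol is exercised on synthetic titration groups;
with real data the groups would be phantom titrations or experiment days,
and the augmentation records would be these same simulated spectra.
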