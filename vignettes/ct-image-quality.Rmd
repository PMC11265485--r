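---
title: "Quantitative CT image quality on a simulated abdomen phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CT image quality on a simulated abdomen phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(ctiq)
```

## What this package measures, and why on a simulated phantom

Comparing CT reconstruction algorithms (classical filtered back projection,
hybrid iterative reconstruction, deep-learning reconstruction) requires more
than a noise number: iterative algorithms reduce noise *magnitude* while
changing noise *texture* and low-contrast edge sharpness, which is exactly
where their clinical risk lies. The standard quantitative battery on a
phantom with a homogeneous insert and a low-contrast lesion rod is:

* **Noise**: the SD of CT numbers in a homogeneous region of interest (ROI).
* **CNR**: contrast-to-noise ratio, $(\mu_1 - \mu_2)/\sigma$, with $\mu_1$
  the homogeneous-insert mean, $\mu_2$ the phantom-background mean and
  $\sigma$ the insert noise.
* **NTD** (noise texture deviation): the fraction of ROI pixels deviating
  more than $3\sigma$ from the ROI mean,
  $f_{3\sigma} = \#\{i : |p_i - \bar p| > 3\sigma\}/n$. Pure Gaussian noise
  gives $2(1 - \Phi(3)) \approx 2.7\times10^{-3}$; the patchy "blotch"
  artifacts typical of iterative reconstruction push it higher.
* **Homogeneity**: the range of the mean CT numbers of the ROIs inside the
  homogeneous insert.
* **NPS**: the radially averaged 2D noise power spectrum of homogeneous
  ROIs, summarized by its power-weighted average frequency
  $f_{avg} = \sum f\,\mathrm{NPS}(f) / \sum \mathrm{NPS}(f)$. Lower
  $f_{avg}$ means coarser, smoother-looking noise.
* **TTF**: the task-based transfer function measured on the circular edge of
  the low-contrast lesion, summarized by $f_{50\%}$, the frequency at which
  the TTF drops to one half.
* **Dose-reduction potential**: from per-algorithm regressions of
  $\ln(\text{noise})$ on $\ln(\text{dose})$, the dose at which a test
  algorithm matches a reference algorithm's noise, with a delta-method
  confidence interval for the saving.

Real reconstruction algorithms are proprietary and live inside scanners, so
this package pairs the analysis chain with a **simulator** that emulates
their measurable signatures on a rendered semi-anthropomorphic abdomen
phantom: an elliptical 35 × 25 cm body (~18 HU) holding a 5 cm homogeneous
insert (~58 HU) and a low-contrast insert (~55 HU) with a 15 mm, ~80 HU
lesion rod of 3 cm axial extent. Every stage of the pipeline can therefore
be validated against known ground truth. The simulator makes no claim to
reproduce any vendor algorithm internally; it reproduces the *statistics*
the analysis is supposed to recover.

## The noise model

A `noise_model()` bundles four measurable signatures:

* **Magnitude**: $\sigma(D, t) = \sigma_{ref}\,(D/D_{ref})^{-1/2}
  (t/t_{ref})^{-1/2}$, the quantum-limited scaling of noise with dose $D$
  (CTDI$_{vol}$, mGy) and slice thickness $t$ (mm). Both exponents are
  configurable; $-1/2$ is the physical default.
* **Texture**: a radial NPS shape. The `fbp-like`/`ir-like` family is the
  ramp-times-Gaussian $S(f) \propto f e^{-(f/f_c)^2}$, the shape that ramp
  filtering plus apodization imprints on reconstruction noise; smaller
  $f_c$ gives the coarser texture typical of iterative blending. `white` is
  available for calibration work. `calibrate_shape()` inverts the
  band-limited analytic $f_{avg}$ of the family by bisection (tolerance
  $10^{-4}$ mm$^{-1}$), so the generator can be pointed at a target
  texture; attainable targets lie below $2/3$ of Nyquist for this family.
* **Edge blur**: a Gaussian point-spread SD (mm) applied to the noiseless
  structure, controlling the TTF.
* **Blotches** (optional): a sparse, zero-mean field of Gaussian bumps with
  Poisson counts and random signs, emulating the non-Gaussian artifacts of
  hybrid iterative reconstruction, the mechanism behind elevated NTD. This
  is an emulation device, not a model of any specific algorithm; its
  parameters (density per mm², amplitude in HU, width in mm) scale with the
  same dose law as the noise.

Noise fields are synthesized by weighting complex white noise with
$\sqrt{S(f)}$ in the 2D Fourier domain, inverse transforming, zeroing the
DC term and rescaling so the sample SD equals the target exactly. Noise is
generated independently per slice (the metrics here are all per-slice; no
inter-slice correlation is modelled). One master seed per scan drives a
documented per-slice counter scheme (`seed + 100003 k` mod $2^{31}-1$), so
any slice is reproducible in isolation and whole designs are reproducible
from one integer.

### Study-condition defaults

`ctiq_study_models()` encodes the seven-algorithm comparison the package is
organized around: FBP at 10 HU noise (25 mGy, 2.5 mm), three hybrid IR
levels and three DLR strengths at 33%, 46% and 60% noise reduction, NPS
average frequencies from 0.31 (FBP-like) down to 0.19 mm$^{-1}$ (strongest
IR), edge blur from 0.55 to 0.87 mm, and blotch artifacts on the IR arms.
The absolute FBP noise level is a realistic abdominal value chosen once
(noise magnitudes are scanner-specific; only ratios and scalings are
asserted anywhere). Pixel spacing defaults to 0.6854 mm, back-computed from
a 41-pixel ROI spanning 28.1 mm; thin-slice (0.625 mm) arms are modelled
solely through the thickness exponent (a factor 2 versus 2.5 mm).

```{r models}
models <- ctiq_study_models()
models$FBP
models$IR90
```

## ROI metrics

The per-slice layout mirrors standard practice: a 41 × 41 px (28.1 mm)
central ROI in the homogeneous insert, four 21 × 21 px (14.4 mm) peripheral
ROIs at 90° spacings, and one 21 × 21 px background ROI. The peripheral
radius defaults to the largest that keeps each ROI fully inside the insert
(their exact placement is not standardized; it is configurable, and overlap
with the central ROI is permitted). NTD is computed per ROI with the sample
SD ($n-1$) and a strict inequality, reported as the average over the five
insert ROIs (a central-only mode exists; published practice does not pin
this down). Homogeneity uses only the five insert ROIs, excluding the
background. Group comparisons use Welch's two-sample t-test, two-sided at
the 5% level — the unequal-variance form is the safe default when arms have
different noise.

```{r roi}
layout <- ctiq_layout()
rois <- roi_set(layout)
stack <- simulate_scan(layout, models$FBP, dose = 25, n_slices = 10, seed = 1)
metrics <- stack_metrics(stack, rois)
round(head(metrics[, c("slice", "noise", "cnr", "ntd", "homogeneity")], 3), 4)
```

## NPS estimation

Four 32 × 32 px ROIs in a quadrant arrangement inside the homogeneous
insert are taken from every slice; each is detrended, Fourier transformed,
and the averaged periodogram is normalized so that white noise of variance
$\sigma^2$ has the flat level $\Delta x\,\Delta y\,\sigma^2$. Radial
averaging uses bins of one DFT bin width, keeps the axis on
$[0, f_{Nyquist}]$, and drops (rather than interpolates) empty bins.
Numerical choices worth stating:

* **Detrending** defaults to a per-ROI first-order polynomial surface,
  which removes the mean and the gradients a semi-anthropomorphic
  background introduces; `"mean"` and `"none"` are selectable. The ROI size
  itself (32 px) is a compromise forced by the 5 cm insert.
* **No spectral window** is applied before the DFT: windowing biases total
  power, and at these ROI sizes detrending already controls leakage.
* Curves from repeat scans are **averaged first, then normalized** to unit
  integral; the reported total power is the 2D Parseval integral, which
  matches the detrended pixel variance to within the detrending loss
  (tested at 15%).

```{r nps}
nps <- estimate_nps(stack, layout)
nps
```

## TTF estimation

The lesion centre is found at subpixel precision as the contrast-weighted
centroid of supra-half-contrast pixels (polarity-agnostic). Pixels from the
ten central lesion slices are pooled into a radial edge spread function
with 0.25 px (0.171 mm) oversampled bins; the profile radius is capped at
1.8 lesion radii so neighbouring structures stay out. The ESF is optionally
made monotone by isotonic pooling (on by default for noisy data, off in
noiseless validation), differentiated by central differences, tapered with
a peak-centred Hann roll-off that leaves the edge core untouched, and
Fourier transformed; the curve is then divided by the known transfer
functions of the bin-average boxcar and the finite-difference
differentiator. `f50` is the interpolated first downward crossing of 0.5;
a curve that never crosses reports `f50 = NA` with `f50_reached = FALSE`,
which is a result, not an error. TTF is computed per scan and averaged
across repeats (slice-level averaging is available; the pooling order is a
genuine free choice).

Against the Gaussian closed form $f_{50} = \sqrt{\ln 2 / (2\pi^2\sigma^2)}$
the chain recovers blur SDs of 0.55–1.2 mm within 5% (about −2% residual
bias at 0.55 mm, shrinking with larger blur); below ~0.5 mm (≈0.7 px) pixel
sampling of the rendered edge limits accuracy. Under study-condition noise
the per-scan $f_{50}$ is unbiased to within ~10% but individual scans
scatter — the low CNR of a 25 HU lesion makes single-scan TTF fragile,
which is precisely why only the highest dose level is analyzed by default.

```{r ttf}
ttf <- estimate_ttf(stack, layout)
ttf
```

## Dose-reduction modelling

Per algorithm, the per-scan mean noise values (3 repeats × 5 doses = 15
points in the full design) are regressed as
$\ln\sigma = a + b\ln D$ by OLS — per-slice fitting is available but
inflates $n$ unrealistically. The equivalent dose of a test algorithm
against a reference at $D_{ref}$ is
$D_{eq} = \exp\{(a_r + b_r \ln D_{ref} - a_t)/b_t\}$, the saving is
$\Delta = D_{ref} - D_{eq}$, and its variance follows from the delta
method through all four coefficients with the block-diagonal covariance of
the two independent fits (propagating the reference fit too is the
conservative choice; a fixed-reference mode exists for sensitivity).
Intervals use the normal 1.96 quantile, matching the delta method's
asymptotics. Percent savings are rounded to integers in printed summaries
only. Monte-Carlo checks (500 simulated designs) put the interval's
coverage at its nominal 95% within sampling error, also when the true dose
exponent is −0.3 rather than −0.5 — the slope is fitted, never imposed.

```{r dose}
doses <- c(5, 10, 15, 20, 25)
noise_ref <- 10 * (doses / 25)^(-0.5)           # an IR50-like reference arm
noise_dlh <- sqrt((25 - 18.4) / 25) * noise_ref # a strong-DLR-like test arm
dr <- dose_reduction(fit_noise_dose(doses, noise_dlh, "DLH"),
                     fit_noise_dose(doses, noise_ref, "IR50"), d_ref = 25)
dr
```

## The pipeline and its validation scope

`run_pipeline()` chains simulate/load → ROI metrics → NPS → TTF → dose
model into CSV/JSON tables with a provenance block (seed, config hash,
version), deterministic and order-independent given the master seed. The
full study-analog design (7 algorithms × 5 doses × 3 repeats × 40 slices
of 2.5 mm) is what the defaults describe; the shipped tests and the
acceptance script run scaled-down versions of the same conditions — 120
slices per arm for CNR ratios, 600 ROIs (10⁶ pixels) for the NTD floor,
500 Monte-Carlo designs for interval coverage, 8–20 slice stacks for
spectral and pipeline checks — sizes chosen so the whole suite validates
every stage in about a minute of compute while keeping Monte-Carlo error
well inside the asserted tolerances.

What passing these tests shows — and what it does not: the simulator
produces stationary, per-slice-independent Gaussian (plus optional blotch)
noise on an ideal piecewise-constant phantom. Real scanner data add
non-stationarity across the field of view, inter-slice correlation from
helical interpolation, beam hardening, scatter, and reconstruction
nonlinearity (especially for DLR at low dose). Results on this testbed
certify the *estimators*; they do not certify any claim about a specific
scanner or algorithm, and dose-reduction figures derived from noise alone
are known to be more optimistic than task-based ones.

## Known limitations

* No sinogram-domain physics: FBP/IR/DLR are emulated, never implemented.
* The TTF chain assumes an isolated circular lesion; it is not a
  high-contrast MTF tool (no wire/bead support).
* NTD's blotch emulation reproduces elevated values qualitatively; the
  true artifact mechanism of any given IR product is not modelled.
* Fixture arrays are stored as float32: the first write quantizes at
  ~10⁻⁵ relative; DICOM storage quantizes HU to 0.5.
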