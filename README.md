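# ctiq — quantitative CT image quality with a synthetic phantom testbed

`ctiq` implements the quantitative image-quality battery used to compare CT
reconstruction algorithms (filtered back projection, hybrid iterative
reconstruction, deep-learning reconstruction) on a semi-anthropomorphic
abdomen phantom, together with a simulator that emulates the algorithms'
measurable signatures so the whole analysis chain can be validated without
scanner data. It is aimed at medical physicists and imaging researchers who
need tested, reproducible implementations of these estimators.

## The metrics

For image stacks in Hounsfield units, per slice and per condition:

- **Noise** — SD of CT numbers in a homogeneous ROI;
- **CNR** — contrast-to-noise ratio, CNR = (μ₁ − μ₂)/σ, with μ₁ the
  homogeneous-insert mean, μ₂ the background mean, σ the insert noise;
- **NTD** — noise texture deviation, f₃σ = #{i : |pᵢ − p̄| > 3σ}/n, the
  fraction of ROI pixels beyond three SDs; Gaussian noise gives
  2(1 − Φ(3)) ≈ 2.7 × 10⁻³, and the blotchy artifacts of iterative
  reconstruction push it higher;
- **Homogeneity** — range of the insert ROI means;
- **NPS** — radially averaged 2D noise power spectrum with its average
  spatial frequency f_avg = Σ f·NPS(f) / Σ NPS(f) (texture in one number);
- **TTF** — circular-edge task-based transfer function of a 15 mm
  low-contrast lesion, with f₅₀ (the frequency where TTF reaches 50%);
- **Dose-reduction potential** — from OLS fits of ln(noise) on ln(dose) per
  algorithm, the equivalent dose D_eq = exp{(a_r + b_r ln D_ref − a_t)/b_t}
  at which a test algorithm matches a reference algorithm's noise, with a
  delta-method 95% CI for the saving D_ref − D_eq.

The simulator renders the phantom geometry (18 HU body, 58 HU homogeneous
insert, 55 HU low-contrast insert with an 80 HU lesion rod), blurs it with a
per-algorithm Gaussian point spread, and adds per-slice colored Gaussian
noise with a prescribed radial NPS shape, dose^(−1/2) and thickness^(−1/2)
magnitude scaling, and optional blotch artifacts. Everything is
deterministic from one integer seed.

## Worked example

```r
library(ctiq)

layout <- ctiq_layout()          # 512 x 512 @ 0.6854 mm, the default phantom
models <- ctiq_study_models()    # FBP, IR50/70/90, DLL/DLM/DLH emulations
rois   <- roi_set(layout)        # 41x41 central, 4 x 21x21 peripheral, background

res <- lapply(models[c("FBP", "IR50", "IR90", "DLH")], function(m) {
  st <- simulate_scan(layout, m, dose = 25, n_slices = 10, seed = 42)
  stack_metrics(st, rois)
})
agg <- aggregate_metrics(do.call(rbind, res), baseline = "FBP")
agg[, c("algorithm", "dose", "noise_mean", "cnr_mean", "relative_cnr", "ntd_mean")]
#>   algorithm dose noise_mean cnr_mean relative_cnr ntd_mean
#> 4       DLH   25      4.010    9.998        2.497 0.002073
#> 1       FBP   25     10.033    4.005        1.000 0.002280
#> 2      IR50   25      6.712    5.988        1.495 0.002268
#> 3      IR90   25      3.981   10.109        2.524 0.002937
```

FBP shows its nominal 10 HU noise and CNR 4 = (58 − 18)/10; the
IR50-emulating arm (33% less noise) gains a relative CNR of ~1.49; the
strong arms (60% less noise) reach ~2.5; NTD sits on the Gaussian floor of
~2.3–2.7 × 10⁻³ for the Gaussian arms and is visibly elevated only for the
blotchy IR90 emulation.

```r
st <- simulate_scan(layout, models$FBP, dose = 25, n_slices = 10, seed = 42)
estimate_nps(st, layout)
#> ctiq NPS: 17 radial bins to 0.73 /mm, f_avg 0.3136 /mm, total power 100.5 HU^2 (poly1 detrend, 40 ROIs)
estimate_ttf(st, layout)
#> ctiq TTF: contrast 24.1 HU, f50 0.3234 /mm
```

The measured f_avg (0.31 /mm) and total power (~100 HU² = 10²) recover the
generator's calibration; f₅₀ reflects the model's 0.55 mm edge blur
(Gaussian closed form: 0.34 /mm, single noisy scan shown).

`run_pipeline(ctiq_config(design = list(), seed = 1))` chains
simulate → ROI metrics → NPS → TTF → dose model over a full factorial
design and writes CSV/JSON report tables; `inst/cli/ctiq.R` exposes
`simulate` / `analyze` / `validate` verbs for shell use. Stacks round-trip
through a raw-float32 + JSON sidecar fixture format or a minimal DICOM
series writer/reader (`write_fixture()`, `write_dicom()`, ...).

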