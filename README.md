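# nirpulse

Noise-robust remote photoplethysmography (rPPG) for **two-band near-infrared
face video**. Cameras in the 780–1000 nm range can monitor heart rate in the
dark, but hemoglobin absorbs weakly there: after the standard
hemoglobin/shade component separation, the pulse signal is routinely buried
in amplified sensor noise. `nirpulse` implements the linear
minimum-mean-squared-error (Wiener) alternative to the plain matrix-inverse
separation, together with the complete downstream chain and the evaluation
metrics needed to quantify the difference. It is aimed at researchers in
camera-based vital-sign monitoring and biomedical image analysis.

## The model

Per video frame, the two band densities (negative-log normalized pixel
values) obey

```
v = F r + n
```

with `r = (hemoglobin, shade)` the pigment components, `F` the 2×2 system
matrix, and `n` sensor noise. The pulse wave is the hemoglobin track of `r`
over time. Two separations are provided:

* **conventional**: `r = F⁻¹ v` — exact without noise, fragile with it,
  because the near-infrared `F` is close to singular;
* **Wiener**: `r̃ = G v` with `G = Rrr Fᵀ (F Rrr Fᵀ + Rnn)⁻¹`, the linear
  estimator minimizing `⟨‖r − r̃‖²⟩` given the pigment second moments
  `Rrr = ⟨r rᵀ⟩` (hemoglobin varied over a physiological range, shade fixed)
  and the noise second moments `Rnn = ⟨n nᵀ⟩` measured from an
  artificial-skin-patch region whose only temporal variation is sensor
  noise. With `Rnn = 0` the two coincide exactly.

Downstream, both hemoglobin tracks pass through smoothness-priors
detrending, a zero-phase Butterworth bandpass ([0.75, 4] Hz), prominence-
filtered peak detection, and `HR = 60 / mean(RR)`. Metrics: Pearson
correlation against a pulse-meter reference, spectral SNR
(`20·log10` of the 0.5–15 Hz vs >15 Hz amplitude ratio), and the absolute
error rate `AER = |HR_GT − HR_EV| / HR_GT × 100 %`.

A synthetic session generator (`synthesize_session()`,
`synthesize_frames()`) produces ground-truthed two-band recordings — and
16-bit TIFF frame stacks — with exactly the statistical structure the model
assumes, so the whole pipeline is testable without camera hardware.

## Worked example

```r
library(nirpulse)

cfg  <- synthetic_config(seed = 1)          # 30 s @ 66.5 fps, f0 = 1.2 Hz
sess <- synthesize_session(cfg)
sess
#> <synthetic_session> 1995 frames @ 66.5 fps, f0 = 1.2 Hz (HR 72 bpm), noise sigma 0.0025

res <- run_pipeline(run_config(sess, seed = 1))
res
#> <pipeline_result>
#>         method      stage correlation   snr_db hr_estimated hr_reference
#> 1 conventional        raw     0.06318  -0.5659           NA           NA
#> 2 conventional  detrended     0.06118  -0.6547           NA           NA
#> 3 conventional bandpassed     0.19972 124.7880        96.37         72.1
#> 4       wiener        raw     0.83915   6.8633           NA           NA
#> 5       wiener  detrended     0.82048   6.4264           NA           NA
#> 6       wiener bandpassed     0.97512 138.0004        71.89         72.1
#>   aer_percent
#> 1          NA
#> 2          NA
#> 3     33.6647
#> 4          NA
#> 5          NA
#> 6      0.2831
```

Reading the table: at this noise level the conventional raw pulse sits at
the white-noise SNR floor (≈ −0.6 dB) with essentially no correlation to
the reference, and its bandpassed peaks give a heart rate off by 24 bpm
(AER 33.7 %). The Wiener raw pulse is already 7.4 dB cleaner, correlates at
0.84 before any filtering, and after the chain recovers 71.89 bpm against a
72.1 bpm reference (AER 0.28 %). The patch-estimated noise sigma
(0.00255 density units) closely matches the generator's true 0.0025.

`run_pipeline(..., out_dir = "run1")` additionally writes per-stage signal
CSVs, the metrics table (CSV/JSON), the estimator provenance sidecar
(`F`, `Rrr`, `Rnn`, `G`, seeds) and a run log. A thin command-line wrapper
with `simulate` / `estimate` / `metrics` verbs lives at
`inst/cli/nirpulse.R`.

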