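# eegsubband

Quantitative screening of diffuse encephalopathy from scalp EEG epochs, for
clinical neurophysiology researchers and signal-processing engineers who
need a tested, reproducible reference pipeline.

Electrographically, encephalopathy replaces the normal posterior alpha
rhythm (8–13 Hz) with prominent slow delta activity (< 4 Hz). The package
turns that physiology into numbers:

* **LPF-TVD denoising** — total-variation denoising
  `argmin_x ½‖y−x‖₂² + λ‖Dx‖₁` solved by majorization-minimization
  (tridiagonal solves in C++), combined with a zero-phase order-2
  Butterworth low-pass of the TV residual (`tvd_mm()`, `lpf_tvd()`).
* **Six-level db4 DWT** — an orthonormal periodized filter-bank cascade
  mapping A6/D6/D5/D4 → delta/theta/alpha/beta at 500 Hz, with an exact
  inverse (`wavedec6()`, `waverec6()`).
* **Relative subband energies** — `E_band = Σc² / E_total`, with
  `E_total = E_A6 + Σ_{l=1..6} E_Dl` (`band_energies()`,
  `build_feature_table()`).
* **Welch t screening** per band, including directly from printed summary
  statistics (`welch_t_from_summary()`, `band_ttests()`).
* **Linear SVM classification** (deterministic dual coordinate descent)
  with sensitivity / specificity / accuracy = TP/(TP+FN), TN/(TN+FP),
  (TP+TN)/N (`train_linear_svm()`, `run_feature_set_comparison()`).
* **Synthetic cohort generator** emulating the published group band-energy
  statistics (232 encephalopathy / 218 normal epochs, 12 s @ 500 Hz), so the
  whole pipeline is testable without patient data (`generate_cohort()`).
* **I/O** — EDF (16-bit) and lossless delimited text with JSON manifests
  (`write_cohort()`, `read_epochs()`), plus a CLI at
  `inst/cli/eegsubband-cli.R`.

## Worked example

```r
library(eegsubband)

params   <- generator_params(seed = 101)          # published-cohort defaults
cohort   <- generate_cohort(params)               # 232 + 218 labelled epochs
features <- build_feature_table(cohort)           # denoise -> DWT -> energies

band_ttests(features)
#>    band           t       df             p
#> 1 delta -40.7821191 447.4894 8.033847e-153
#> 2 theta  -0.9268365 421.9269  3.545413e-01
#> 3 alpha  37.6521067 445.2463 1.798142e-140
#> 4  beta  30.6843176 288.0754  8.877823e-93

run_feature_set_comparison(features, seed = 102)
#>   subset  TP  TN FP FN sensitivity_pct specificity_pct accuracy_pct
#> 1    all 129 118  0  3        97.72727       100.00000         98.8
#> 2  delta 129 112  6  3        97.72727        94.91525         96.4
#> 3  alpha 122 117  1 10        92.42424        99.15254         95.6
#> 4   beta 102 118  0 30        77.27273       100.00000         88.0
```

Reading: delta and alpha separate the groups strongly (encephalopathy mean
delta fraction is about twice the normal one; alpha collapses), theta does
not (p = 0.35), and a delta-only linear SVM already screens at 96 % accuracy
on the 250 held-out epochs (100 per group were used for training). On real
EEG the published delta-only figures are lower (sensitivity 91.67 %,
specificity 88.98 %, accuracy 90.4 %) — the synthetic world is cleaner than
patients are; see the vignette for exactly what it does and does not
emulate.

Published summary statistics can be screened directly, without raw data:

```r
welch_t_from_summary(31.39, 10.34, 218, 67.73, 19.34, 232, band = "delta")
#> Welch t [delta]: t = -25.0611, df = 357.7, p = 9.65e-81
```

## Layout

```
R/            synth, denoise, wavelet, features, stats, classify, io, pipeline
src/          MM-TVD and SVM coordinate-descent solvers (Rcpp)
tests/        testthat suite incl. acceptance criteria + independent oracles
vignettes/    methods and design notes
scripts/      acceptance.R
inst/cli/     command-line front end
```
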