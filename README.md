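# mecg — cardiac signal extraction and HRV from MEG recordings

MEG sensor arrays record the magnetic fields of the heart alongside those
of the brain; standard preprocessing discards the cardiac part as noise.
`mecg` recovers it instead: it isolates an MEG-derived electrocardiogram
(**M-ECG**) from multichannel recordings, detects R-peaks, repairs the
RR-interval series, and computes heart rate variability (HRV) — giving any
MEG study, including archival data without an ECG channel, a cardiac
dimension. It is written for neurophysiologists and methods researchers
working with CTF/Elekta-style MEG data or any multichannel recording with
a cardiac signature.

Two extraction routes are supported, and both can run in one pipeline:

* **C-IC** — FastICA over a temporal-channel subset; the cardiac
  independent component is surfaced by an advisory periodicity/kurtosis
  ranking (final choice remains a user parameter).
* **REF** — the reference (noise-cancellation) sensor with the strongest
  cardiac signature, a computationally light alternative that skips ICA.

## The method in brief

After resampling to 600 Hz and zero-phase FIR bandpass (0.5–45 Hz), the
selected trace is baseline-corrected, normalized and wavelet-denoised
(symlet-4, level-3 approximation only). R-peaks are found in two stages:
candidate local maxima with a 0.5 s minimum spacing, then an adaptive
amplitude gate that keeps peaks with

```
mu_A - n*sigma_A <= A_i <= mu_A + n*sigma_A        (default n = 2)
```

where `mu_A`, `sigma_A` are the population mean and SD of the candidate
amplitudes. RR intervals `RR_i = t_{i+1} - t_i` are paired with cumulative
times `x_i = sum(RR_k, k <= i)`; intervals outside
`mu_RR ± 1.5·sigma_RR` are flagged and restored by linear interpolation
over the (never recomputed) `x` axis, so no data points are trimmed. HRV
is reported in the time domain (SDNN, RMSSD, CV, percentile CI) and in the
frequency domain (Welch PSD of the 850-point cubic-spline tachogram, with
VLF/LF/HF band powers). Against an independently recorded ECG (**I-ECG**),
the package computes sequential peak pairing with a signal-quality gate
(<3% misaligned pairs at 0.02 s, ≥98% beat count agreement), detection
benchmarks (sensitivity/PPV/F1 at ±0.05 s), Bland–Altman limits of
agreement, Spearman correlation, Mann–Whitney U tests, Lin's concordance
in 30-beat windows, and dynamic time warping.

A seeded synthetic generator (`synthetic_spec()`, `simulate_recording()`)
produces ECG-like traces with known R-peak times, LF/HF-modulated RR
variability, and noisy multichannel mixtures, so the entire pipeline is
testable without any external dataset.

## Worked example

```r
library(mecg)

sim <- simulate_recording(synthetic_spec(seed = 0))   # 5 min, 27 ch, ~10 dB
res <- run_pipeline(sim$recording, mode = "both",
                    compare_to = sim$ground_truth$true_peak_times_s)
res
#> <pipeline_result> mode=both | stages: load -> bandpass -> ica -> cic_detect -> ref_detect
#>   [cic] status: ok | F1 0.9973 | mean RR 0.798 s, SDNN 0.0223 s
#>   [ref] status: ok | F1 0.9973 | mean RR 0.798 s, SDNN 0.0219 s

res$paths$ref$metrics
#> mean RR 0.798 s | SDNN 0.0219 s | RMSSD 0.0183 s | CV 0.0274 | 95% [0.760, 0.837] s

res$paths$ref$comparison
#> <comparison_stats> n=373 | rho 0.974 | RMSE 0.005479 s | MAE 0.002948 s | DTW 0.08145 s
#>   Bland-Altman -0.0004907 s [-0.01119, 0.01021] | MWU(RR) U=68677.0 p=0.763 | CCC meanRR 0.819, RMSSD 0.713 (12 windows)
```

The F1 of 0.997 says both extraction paths recover essentially every true
beat within ±0.05 s (the two structural misses are the first/last beats at
the recording edges); SDNN ≈ 0.022 s matches the programmed LF + HF + jitter
variability; and the millisecond-scale RMSE/MAE with Spearman ρ ≈ 0.97 and
a near-zero Bland–Altman bias shows the M-ECG RR series is practically
interchangeable with the ground truth.

A thin CLI wraps the same functions:

```sh
inst/cli/mecg simulate --duration 300 --rate 600 --seed 0 --out rec.csv
inst/cli/mecg detect --in rec.csv --channel ECG --out peaks.csv
inst/cli/mecg run --in rec.rds --mode both --compare-channel ECG --outdir out/
```

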