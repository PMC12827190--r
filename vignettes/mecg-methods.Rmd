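---
title: "Extracting cardiac signals and HRV from MEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting cardiac signals and HRV from MEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecg)
```

## The problem

MEG sensor arrays sit close enough to the torso that every recording
carries, superimposed on the neural fields, the magnetic signature of the
heartbeat. Conventional preprocessing treats that signature as an artifact
and removes it; `mecg` instead recovers it as a usable cardiac signal — an
MEG-derived electrocardiogram (M-ECG) — and computes heart rate variability
(HRV) from it. Two extraction routes are provided:

* **C-IC**: FastICA decomposition of a temporal-channel subset; the
  independent component with the most cardiac-like morphology is the
  cardiac independent component.
* **REF**: MEG systems carry reference (noise-cancellation) sensors that
  record strong cardiac fields; the best of these is used directly. This
  route skips ICA entirely and is the computationally light option.

Either trace is then normalized, wavelet-denoised, and run through a
two-stage R-peak detector; the resulting RR-interval series is repaired by
statistical outlier flagging and interpolation, and standard time- and
frequency-domain HRV indices are computed. When an independently recorded
ECG (I-ECG) is available, an agreement suite quantifies how close the
M-ECG-derived HRV comes to the electrical ground truth.

## Pipeline and parameters

`run_pipeline()` executes, in order: load, resample to `resample_rate`
(default 600 Hz, Fourier-domain, downsampling only), zero-phase FIR
bandpass (`band_low` 0.5 Hz to `band_high` 45 Hz, Hamming window), source
extraction (ICA with `ica_n_components = 15`, seed 0, or reference-channel
selection), baseline correction and normalization (subtract mean, divide by
max absolute value, so R-peaks sit near ±1 and every amplitude threshold
below is scale-free), symlet-4 wavelet denoising (3 levels, details
discarded), R-peak detection, RR correction, HRV metrics and spectra.

Parameters that matter, with units and defaults:

| parameter | default | meaning |
|---|---|---|
| `min_distance_s` | 0.5 s | minimum inter-peak distance (one beat per cardiac cycle; caps detectable rate at 120 bpm) |
| `n_amp` | 2 | amplitude gate half-width in candidate-amplitude SDs |
| `n_rr` | 1.5 | RR outlier band half-width in RR SDs |
| `tachogram_points` | 850 | even resampling length of the RR tachogram |
| `misalign_threshold_s` | 0.02 s | peak-pair offset counted as misaligned |
| gate | 3% / 98% | max misaligned share / min beat-count agreement |
| `benchmark_tolerance_s` | 0.05 s | match window for sensitivity/PPV/F1 |

### The two-stage detector

Candidate peaks are interior local maxima (a plateau reports its first
sample) visited in order of decreasing amplitude; a candidate is kept only
when every already-kept peak is at least `min_distance_s` away, with
equal-amplitude ties resolved toward the earlier peak so results are
deterministic. Over the kept candidates the population statistics
\(\mu_A, \sigma_A\) (1/N forms) are computed once, and the second stage
retains exactly the peaks inside \([\mu_A - n\sigma_A,\ \mu_A + n\sigma_A]\)
in a single pass — the gate is not iterated to convergence. Because the sign
of an ICA component is arbitrary, the trace is negated before detection
whenever \(|\min| > |\max|\); detection is therefore sign- and
scale-invariant.

The statistics are computed on the spacing-enforced candidate set (rather
than on all raw local maxima): that is the set the detector actually
considers, and it keeps \(\sigma_A\) from being inflated by sub-beat noise
maxima.

### RR correction

RR intervals \(RR_i = t_{i+1} - t_i\) are paired with the cumulative axis
\(x_i = \sum_{k \le i} RR_k\), fixed **before** correction. Intervals
outside \(\mu_{RR} \pm n\,\sigma_{RR}\) (population moments, evaluated once
on the original series — no re-flagging after correction) are replaced by
linear interpolation of RR against \(x\) between the nearest unflagged
neighbours. Two boundary rules the statistics above do not determine are
fixed as: a flagged first/last interval takes the nearest valid value
(constant extension), and a run of consecutive flags is bridged by a single
linear segment. The interval count never changes — no data are trimmed —
and the untouched \(x\) axis preserves physiological timing.

### Tachogram and spectra

The corrected series is interpolated with a **natural** cubic spline (the
generic "cubic spline" leaves the end conditions open; natural ends are the
least-assumptive choice and are documented so results are reproducible)
at 850 evenly spaced points over \([x_1, x_{last}]\). The resulting uniform
rate \((850-1)/\mathrm{span}\) is reported exactly rather than rounded to a
nominal value; it is about 2.4 Hz for a 6-minute recording. Welch PSD uses
a periodic Hamming window, segment length 256, per-segment constant
detrending, no overlap, one-sided density scaling; band powers are
trapezoid integrals over VLF (0.0033–0.04 Hz), LF (0.04–0.15 Hz) and HF
(0.15–0.4 Hz). VLF is always reported but flagged non-interpretable unless
the tachogram spans at least ten cycles of the VLF lower edge (~50 min);
at the 5–6 minute durations this pipeline targets it is never
interpretable. The Morlet CWT uses the analytic wavelet with
centre-frequency parameter 6 on a log-spaced scale grid.

### Agreement suite

M-ECG peaks are paired to I-ECG peaks by order-preserving greedy matching:
each M-peak takes the nearest I-peak at or after the previously consumed
one, each I-peak used at most once, equidistant ties to the earlier peak.
Beat count agreement is `100·min(n_m, n_i)/max(n_m, n_i)` (the metric is
named in the HRV literature without a formula; the min/max ratio is this
package's operationalization). The quality gate fails a recording when ≥3%
of pairs exceed 0.02 s offset or beat agreement falls below 98%; a gate
failure is a *result* (status `"insufficient cardiac signal quality"`),
never an exception, mirroring how low-quality recordings are excluded from
HRV analysis rather than crashing a batch.

Bland–Altman limits of agreement use the conventional 1.96 multiplier on
the population SD of the differences (M − I). Lin's concordance is
computed on per-window mean RR and RMSSD over non-overlapping 30-interval
windows (SDNN is deliberately not windowed: it is unreliable over 30
intervals). In the pipeline, element-wise statistics are computed on the
*beat-paired* series — both RR series are rebuilt from the matched peak
pairs, so interval *k* describes the same heartbeat in both; without this,
a single missed edge beat shifts one series by an interval and
decorrelates the whole comparison. `comparison_stats()` itself simply
truncates whatever two series it is given to their common length; dynamic
time warping is the designated length-tolerant comparison and returns the
square root of the minimal accumulated squared difference along the
warping path. The Mann–Whitney U test is applied to the RR distributions
and, separately, to the Welch PSD values on the common frequency grid.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` defines the study conditions: 5-minute recordings,
mean RR 0.8 s (75 bpm), LF modulation 0.1 Hz × 30 ms, HF modulation
0.25 Hz × 20 ms, Gaussian beat jitter of 5 ms, 27 MEG channels with
weights U(0.5, 1.5), ~10 dB mean channel SNR, a reference channel at twice
the mean weight (reference sensors carry the most robust cardiac
signature), and a near-noise-free ECG channel. RR intervals follow a
sinusoid-plus-jitter model evaluated self-consistently at each beat's own
cumulative time — chosen over an integral-pulse-frequency-modulation model
because it has closed-form expectations (an RR sinusoid of amplitude *a*
contributes SD *a*/√2, and a known spectral line) that validation tests
can check exactly. QRS complexes are unit Gaussian bumps (SD =
`qrs_width_s`/4) with a smaller T-wave; real digitized beats would add
realism but no testability.

R-peak **amplitudes** carry a bounded sinusoidal modulation (default 10%
at the HF/respiratory frequency). This matters: real R-amplitude
variability is respiration-dominated and bounded, and the
\(\mu_A \pm 2\sigma_A\) gate behaves correctly for such distributions. A
generator with constant amplitudes plus Gaussian noise would make the gate
reject a fixed ≈4.5% of true beats at any noise level (the tail mass of a
Gaussian beyond 2 SDs does not depend on its scale), which is a property
of that unphysiological amplitude model, not of the detector.

What the generator does **not** emulate: neural background with realistic
spectra (channel noise is white), volume-conduction geometry (mixing is a
random weight vector, not a forward model), respiration-coupled baseline
drift, ectopic beats and arrhythmia, and movement artifact. Passing tests
therefore demonstrate algorithmic correctness and noise robustness at
realistic SNR — not clinical validity on pathological rhythms, which the
detector's fixed 0.5 s spacing and single-pass amplitude gate are not
designed for.

## Numerical choices

* **FIR design**: Hamming-window bandpass; transition bands
  `min(max(0.25·f, 2 Hz), f)` at the low edge and analogously (bounded by
  the Nyquist gap) at the high edge; length `3.3·rate/min(transition)`
  rounded to odd; −6 dB points half a transition outside the passband
  edges; the DC tap sum is zeroed exactly. Zero phase is achieved by
  single-pass FFT convolution with the group delay removed — not by
  forward–backward filtering, which would square the magnitude response.
  Edges are padded by odd reflection; the outer half-filter-length of
  signal still carries boundary transients.
* **Resampling** is Fourier-domain spectrum truncation with ~1 s of odd
  reflection padding; only downsampling is supported.
* **DWT**: symlet-4 with symmetric signal extension and redundant boundary
  coefficients, so analysis/synthesis reconstructs exactly; denoising keeps
  the level-3 approximation only (0–rate/16).
* **FastICA**: PCA whitening to 15 dimensions, symmetric logcosh updates,
  tolerance 1e-4, 200 iterations max, seeded initial matrix. The unmixing
  matrix is estimated on every 3rd sample — FastICA consumes only marginal
  sample statistics, so decimation speeds estimation without bias — and
  sources are reconstructed at full rate. With one non-Gaussian source
  among Gaussian noise directions the iteration cannot fully converge (the
  noise subspace has rotational freedom); the cardiac direction stabilizes
  within a few iterations regardless.
* **Ties and degenerate inputs**: spacing ties keep the earlier peak;
  plateaus report their first sample; a constant trace is a degenerate
  error for normalization; a zero-width amplitude band (σ = 0) retains
  everything (all amplitudes equal μ); an all-flagged RR series is
  unusable; Spearman/CCC on constant series raise errors naming the
  statistic rather than returning NaN.
* **Component ranking**: score = 0.7 × periodicity (autocorrelation peak in
  the 0.5–1.5 s lag band) + 0.3 × k/(k+10) for excess kurtosis k.
  Periodicity is weighted higher because it is the stronger cardiac
  signature; the kurtosis squash keeps spiky but aperiodic artifacts from
  dominating. The ranking is advisory — the component choice remains a
  user parameter, reflecting that visual inspection is the reference
  practice for C-IC selection.

## Statistical calibration note

The Mann–Whitney calibration study draws its null pairs from a jitter-only
generator (LF and HF amplitudes zero). The U test assumes independent
observations; sinusoidally modulated RR series are strongly autocorrelated,
so using them in the null would measure the effect of serial dependence on
the test, not the test's nominal behaviour. The jitter-only null isolates
calibration: rejection at α = 0.05 occurs in ~5% of replicates. On real,
autocorrelated RR data the U test's p-values remain descriptive, which is
how they are used here (reporting similarity of distributions, not
confirmatory inference).

## Problem sizes used in validation

The bundled tests validate the full study conditions (five 5-minute
27-channel studies for detection, ten for ICA recovery, 300 replicates for
the Mann–Whitney null) and use compact studies (60 s, 200 Hz, 12 channels)
for unit-level checks where the full scale adds nothing. The oracle
comparisons run the detector against a literal brute-force implementation
on traces up to 5,000 samples, and DTW against exhaustive path enumeration
up to length 8, where enumeration is tractable.

## Known limitations

* Native FIF/CTF reading delegates to MNE-Python through a bridge script;
  an R-native reader for those binary formats is not provided. CSV and the
  package's own serialized container are first-class.
* The detector assumes a dominant, upright-or-inverted R deflection; biphasic
  QRS morphologies or rates above 120 bpm (spacing floor 0.5 s) need
  parameter changes.
* Outlier correction repairs isolated missed/spurious beats; sustained
  arrhythmia violates its smooth-RR assumption.
* VLF power is computed but never interpretable at the target durations.
* The 850-point tachogram makes the uniform rate depend on recording span;
  spectra from recordings of very different lengths have different Nyquist
  ranges.
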