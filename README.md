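# bioqc

Quantitative quality assessment of multimodal biopotential recordings
(ECG, EMG, EEG) in R — for anyone validating electrode hardware or
screening physiological recordings before downstream analysis: does a
channel carry a clean cardiac signal, force-graded muscle activity, a
detectable alpha rhythm? The package answers with reproducible numbers
rather than visual impressions.

## What it computes

**ECG quality.** Three signal-quality indices on the preprocessed trace
(zero-phase 0.3–100 Hz band-pass + 60 Hz notch; baseline index on a
notch-only copy):

- kSQI — Pearson kurtosis `E[(x−μ)⁴]/σ⁴`; excellent above 5,
- pSQI — QRS-band relative power `∫₅¹⁵P(f)df / ∫₅⁴⁰P(f)df`; excellent
  in [0.5, 0.8],
- basSQI — `1 − ∫₀¹P(f)df / ∫₀⁴⁰P(f)df`; excellent near 1.

A fuzzy comprehensive evaluation maps the triplet through
Cauchy/rectangular/trapezoidal memberships onto three quality levels,
composes the fuzzy vector `s_j = min(1, Σᵢ wᵢ rᵢⱼ)` (bounded sum), and
scores

    v = Σⱼ sⱼ² · j / Σⱼ sⱼ²,   grade: E if v ≤ 1.50, B if 1.50 < v < 2.40, U if v ≥ 2.40,

with a three-route decision workflow (accept / denoise-and-re-evaluate /
re-record).

**HRV.** Two-moving-average R-peak detection (8–20 Hz band, 97/611 ms
windows), windowed P-QRS-T delineation, NN outlier filtering, time-domain
parameters (mean NN, rate, RMSSD, pNN50, Poincaré SD1, both SDNN
conventions) and frequency-domain band powers (VLF/LF/HF/VHF from the
4 Hz-resampled NN series), plus a seeded random-slice comparison of two
channels.

**EEG.** STFT spectrogram, sliced pre/post-event FFT, and an alpha-band
(8–13 Hz) presence detector based on a per-Hz flank-power ratio, with
peak-to-peak amplitude estimates from the analytic envelope.

**Channel metrics.** `snr()` (`20·log10` of the RMS ratio against a
designated noise epoch or trace) and `xcorr()` (zero-lag normalized
inner product).

**Synthetic generator.** ECG (Gaussian P-QRS-T kernels on an
LF/HF-modulated NN process), force-graded EMG bursts, state-dependent
EEG alpha, and exact-SNR noise injection — each with ground truth, the
basis of the validation suite.

## Worked example

```r
library(bioqc)

nn    <- generate_nn_series(150, seed = 42)          # ~2 min of beats
ecg   <- synthesize_ecg(nn)                          # clean trace + R truth
noisy <- add_noise(ecg, baseline = c(0.3, 5), powerline = c(60, 3),
                   target_snr_db = 25, seed = 43)

tri <- compute_sqi(noisy$signal)
round(tri, 4)
#>    ksqi    psqi  bassqi
#> 14.6831  0.7273  0.9672

fuzzy_evaluate(tri)
#> <bqc_fuzzy> v = 1.1777  grade = E  (kSQI 14.68, pSQI 0.73, basSQI 0.97)
quality_decision(fuzzy_evaluate(tri), tri)
#> [1] "accept"

pk <- detect_r_peaks(preprocess_ecg(noisy$signal))
str(lapply(hrv_time(nn_intervals(pk)), round, 3))
#> $ mean_nn          : num 850      # ms
#> $ ecg_rate_mean    : num 70.6     # bpm
#> $ rmssd            : num 25.3     # ms
#> $ sdnn_printed     : num 25.3     # ms (SD of successive differences)
#> $ sdnn_conventional: num 26.9     # ms (SD of the NN intervals)
#> $ pnn50            : num 4.73     # %
#> $ sd1              : num 17.9     # ms

snr(ecg, noisy$noise)                                # ground-truth noise trace
#> <bqc_snr> 25.00 dB (signal RMS 163, noise RMS 9.15)
```

The record passes all three index criteria (kurtosis well above 5,
QRS-band power inside [0.5, 0.8], baseline power negligible), grades
Excellent with `v = 1.18`, and is accepted; the injected noise is
recovered at exactly the requested 25 dB.

`bqc_demo(seed = 0)` runs the full synthetic wet/dry ECG + EMG + EEG
reproduction end-to-end and returns (optionally writes) the combined
quality report. A thin command-line wrapper lives at
`inst/cli/bioqc.R`.

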