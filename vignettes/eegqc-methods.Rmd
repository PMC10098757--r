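---
title: "Methods: quality metrics, wavelet band energies, and the synthetic two-device session"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality metrics, wavelet band energies, and the synthetic two-device session}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegqc)
```

This vignette is the package's account of its own methods: the models and
conventions it commits to, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical choices underneath.

## The validation problem

Two EEG devices record the same routine clinical session — a wearable
dry-electrode headset (16 channels, 125 Hz, ear-referenced) and a clinical
machine (21 channels, 500 Hz, vertex-referenced). The question is whether
the wearable's signal quality and its rendering of the protocol responses
(alpha reactivity, hyperventilation slowing, photic driving) are consistent
with the clinical reference. The package answers it with three instruments:
a power-frequency noise model with SNR/PSNR/MSE, a dyadic wavelet
band-energy decomposition, and quantitative stimulus-response indices.

## Pre-processing

Each recording is segmented per test over half-open intervals
`[round(t_start*fs), round(t_end*fs))`, then each channel is band-pass
filtered with an order-5 Butterworth design between `f_low = 0.5` and
`f_high = 40` Hz, then normalized. Stages move strictly
raw → filtered → normalized, and the affine normalization factors are
retained so the raw signal can be brought onto the cleaned scale.

**Zero-phase filtering.** The filter direction is applied
forward-backward by default so waveform morphology is preserved for visual
review; the effective magnitude response is then the square of the
single-pass response, and a `zero_phase = FALSE` flag gives the literal
single-pass filter. Each pass is initialized at the steady state the filter
would reach under a constant input equal to the first padded sample —
algebraically, the offset-removed sequence is filtered and the DC-gain
response added back — with odd-reflection padding of three filter lengths.
This suppresses the startup transient entirely (a DC input is attenuated to
below 10⁻⁹ of its amplitude); residual edge ringing from the reflection
kink at an arbitrary end phase is unavoidable for finite segments, so
steady-state measurements in the tests trim two seconds per edge.

**Normalization.** The method is `peak_unit` by default: each channel is
divided by its maximum absolute value, so the cleaned signal's peak term in
the PSNR is exactly 1 and `psnr_db == -20*log10(mse)`. A `zscore` option
(mean 0, sample SD 1) is retained. `peak_unit` was chosen as the default
because it is the most parsimonious convention under which SNR and PSNR
summaries coincide column-wise in a device × test quality table, which is
how such tables are conventionally reported.

## The noise model and the quality triad

Noise is defined as what the band-pass removes: baseline wander below
0.5 Hz plus high-frequency content above 40 Hz (powerline interference
included). Rather than band-isolating those ranges separately, the noise
component is computed as the residual `N = a_scaled - b`, where `a_scaled`
is the raw channel brought onto the cleaned channel's normalization scale.
With a band-pass-defined cleaned signal the two definitions coincide up to
filter roll-off, and the residual form makes the power bookkeeping
`P_a = P_b + P_N + cross-term` explicit and directly testable.

- `snr_db(P_a, P_N) = 10 log10(P_a / P_N)`; `P_N = 0` yields a `+Inf`
  sentinel which is flagged, excluded from averages, and counted in a
  warning — never silently dropped. `P_a = 0` is a degenerate-signal error.
- `mse(a, b)` is the plain mean squared difference.
- `psnr_db(MAX_f, MSE) = 20 log10(MAX_f / MSE)` with the **MSE itself** in
  the denominator. That form — not the conventional RMSE form — is the
  package's reference definition; `literature = TRUE` computes
  `20 log10(MAX_f / sqrt(MSE))` for comparison with the image-processing
  convention. The two are reported side by side and never forced equal.

**Aggregation order.** Channel values are averaged per subject first, then
the mean and sample standard deviation (n − 1) are taken across subjects
for each device × test cell. A single-subject cell reports `NA` for the SD,
not 0. Channels-first aggregation keeps channel-wise variation (which is
reference-montage dependent) out of the between-subject spread.

## Wavelet band energies

The five clinical bands are realized as dyadic octaves of a multilevel DWT:
halving the Nyquist frequency until the residual approximation falls at or
below 4 Hz gives, at 125 Hz (depth 4), delta 0–3.9 / theta 3.9–7.8 /
alpha 7.8–15.6 / beta 15.6–31.3 / gamma 31.3–62.5 Hz, and at 500 Hz
(depth 6) the same edges with two extra, unassigned top octaves. The dyadic
edges — not the clinical textbook definitions (alpha 8–12 Hz etc.) — are
what a DWT can deliver, and the mismatch is carried in every output table
via the explicit `f_lo`/`f_hi` columns. Signals are analyzed at their
native rate; the clinical device is never resampled down.

**Level numbering.** Components are labelled in the standard convention
where detail 1 spans fs/4–fs/2. Report layouts that number levels with a +1
offset (counting the raw signal as the first level) can be reproduced with
`level_convention = "legacy"`; the frequency edges, which are
convention-independent, are authoritative.

**Transform.** The package implements the orthonormal pyramid algorithm
directly, with periodized boundary handling. Periodization was chosen over symmetric extension
because it keeps the analysis operator exactly orthogonal: reconstruction
is the adjoint, sub-band reconstructions are mutually orthogonal, and the
five-band energy sum equals the total signal energy to floating-point
precision (the 2% tolerance quoted in tests covers only the truncation of
the analysis length to a multiple of 2^depth). Energies are computed from
the reconstructed sub-band time series so all bands share the time axis.

**Wavelet choice.** The default mother wavelet is db10 (configurable
db2–db10). Shorter members have wide transition bands: a pure 10 Hz tone —
the canonical alpha test case — concentrates only ~84% of its energy in
the alpha octave under db4, versus ≥90% under db10. Even db10 cannot make
tones sitting 10–15% from a dyadic edge concentrate 90% of their energy
in-band; dyadic filter-bank transition zones span roughly ±20–25% of each
edge frequency regardless of Daubechies order. The dominant-band
assignment, however, matches an FFT oracle across a 1–45 Hz tone grid
(edge-adjacent tones excluded), and that is the property the band tables
rely on.

## Response indices

These are the package's quantitative operationalizations of responses that
clinical review verifies visually; outputs label them as derived
observables, not standard clinical statistics. All three are band-power
ratios and hence invariant to rescaling the recording.

- **Alpha reactivity**: mean occipital alpha power (8–13 Hz, Welch) during
  eyes-closed intervals divided by the same during eyes-open intervals;
  values above 1 indicate normal alpha blocking.
- **HV slowing index**: `[(delta+theta)/(alpha+beta)]_HV` relative to the
  same ratio at baseline, from DWT band energies averaged over the
  requested channels.
- **Photic driving**: per stimulus step, a Welch spectrum (2 s Hann
  windows, 50% overlap — 0.5 Hz resolution, matching the ±0.5 Hz scoring
  window; ~9 windows fit a 10 s step) averaged over the occipital
  channels. The score is the power within ±0.5 Hz of the stimulus
  frequency (plus the second harmonic when it lies at or below 40 Hz)
  divided by the median broadband power over 1–40 Hz; the detected
  frequency is the spectral argmax in 1–40 Hz. Steps shorter than two
  stimulus cycles are flagged low-confidence. Scores are reported, never
  dichotomized into "driving present/absent".

## The synthetic session generator

The study design the generator emulates is a *paired* protocol: both
devices record the same brain. One latent 21-channel source process is
synthesized at 1000 Hz (at least twice the fastest device), then anti-alias
filtered (linear-phase FIR, cutoff at 90% of the target Nyquist, exact
integer group delay removed) and decimated to each device's rate; device
noise is added afterwards. Every component is additive and the component
ledger can be retained, so oracle tests can interrogate each ingredient
separately — the ledger sums to the composite exactly.

Defaults, chosen once as physiologically plausible calibration constants
(no amplitude statistics were available to copy):

| component | default | notes |
|---|---|---|
| background | 1/f, exponent γ = 1, 10 µV rms | per-channel independent plus a 20% shared common-mode term mimicking reference-montage correlation |
| occipital alpha | 10 ± 2 Hz narrowband, 2 µV rms, ×3 while eyes closed | occipital weights 1, parietal 0.5, elsewhere 0.1; 0.25 s raised-cosine envelope transitions |
| HV slowing | 2–7 Hz narrowband, ramp 0 → 10 µV rms across HV | bifrontal preponderance (frontal weights 1, elsewhere 0.6) |
| photic driving | 6 µV sinusoid at the stimulus frequency, 30% second harmonic | 0.2 s on/off ramps per step |
| blinks | 10/min, 80 µV, 300 ms biphasic raised-cosine pulses | frontal only; a stylized stand-in, not a physiological waveform model |
| wearable noise | 50 Hz powerline 8 µV, drift 20 µV rms (0.02–0.4 Hz), white 0.3 µV | dry-electrode, ear-referenced device |
| clinical noise | powerline 2 µV, drift 8 µV rms, white 0.3 µV | gel-electrode reference device |

Powerline defaults to 50 Hz (configurable to 60 Hz). The protocol defaults
are 60 s baseline, 240 s EOC (alternating 10 s states; twelve cycles fill
the 4-minute segment), 180 s HV, and the 12-step photic schedule 1, 3, 6,
8, 10, 12, 14, 16, 18, 20, 25, 30 Hz × 10 s. The seed fully determines the
output, bit for bit.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no volume conduction or forward head model, no
electrode-impedance dynamics or motion artifacts, no non-stationary
background beyond the scripted protocol responses, no epileptiform
morphology. It establishes that the *pipeline* recovers known ground truth,
not that any particular hardware is clinically adequate.

## Known limitations and degenerate cases

- **Cross-device gamma energies.** Designing the same analog Butterworth
  specification at 125 Hz and at 500 Hz by bilinear transform yields
  digital filters whose responses differ inside 31–40 Hz (the 125 Hz
  design warps sharper toward its Nyquist); weighted by a 1/f spectrum,
  the zero-phase gamma-octave response ratio is ≈1.19. Band-energy
  profiles of the two simulated devices therefore agree within ~10%
  relative in delta–beta but differ by ~11–15% in gamma. This is inherent
  to filtering each device at its native rate and is a genuine caveat on
  cross-device "consistency" claims for the gamma band.
- Finite-segment zero-phase filtering rings near segment edges when the
  end phase breaks the odd reflection; steady-state quantities should be
  measured away from edges.
- All-zero (or constant, under z-scoring) channels are rejected by name
  rather than producing NaN scales; zero-noise channels produce `+Inf`
  SNR/PSNR sentinels that are excluded from summaries with a warning.
- DWT analysis truncates each channel to a multiple of 2^depth samples
  (at most 0.5 s of a 500 Hz segment at depth 6).
- EDF output quantizes to 16 bits over the observed per-channel amplitude
  plus 5% headroom; round-trip error is bounded by one quantization step.

## Problem sizes used by the test suite

Unit and property tests run on 10–120 s single- or two-channel segments.
The end-to-end acceptance checks simulate five full default-protocol
sessions (600 s, two devices, 16 + 21 channels) and run the complete
pipeline on each; the acceptance script does the same for one session at
the caller's seed. These sizes were chosen so the statistical properties
under test (spectral slopes, band fractions, detection counts) are stable
across seeds while a complete run stays in the minutes range on one CPU.
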