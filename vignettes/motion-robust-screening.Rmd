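---
title: "Motion-robust arrhythmia screening: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-robust arrhythmia screening: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ecgfuse)
```

## The problem and the model

Wearable single-lead ECG is corrupted by electrode-motion artifacts whose
spectral content overlaps the QRS band, so an ECG-only classifier cannot
reliably separate motion-distorted normal beats from genuine ectopy. The
package couples the ECG with a synchronized tri-axial accelerometer and
learns, per sample, how much to trust each modality.

The pipeline is: condition the ECG (fourth-order Butterworth band-pass,
zero-phase, realized as cascaded second-order sections; then z-normalization
over a 10 s sliding window with symmetric edge padding and a standard
deviation clamp at 0.01 so flat-line segments map to zero), detect R-peaks
(Pan–Tompkins front end — five-point derivative, squaring, 150 ms integration
— with the adaptive threshold `NPKI + 0.25 (SPKI − NPKI)` and 0.125/0.875
exponential peak trackers, a 200 ms refractory period, and refinement of each
detection to the local extremum of the filtered ECG within ±50 ms), cut 1 s
beat windows centered on R-peaks, and classify each window with the
dual-stream network described in the README: a residual spectrogram encoder
(512-d features), a CNN-BiLSTM accelerometer encoder (128-d features plus a
4-class motion-intensity head), scalar sigmoid attention gates per modality,
and a softmax head over the gated concatenation.

Gate collapse — the gates converging to constants, which silently turns
adaptive fusion into fixed weighting — is prevented by a hinge on the
within-batch standard deviation of each gate,
`max(0, τ − σ_batch(g))` per modality with τ = 0.3, weighted by λ = 0.1 in
the total loss. The hinge is inactive once diversity exceeds τ, so it guides
early training and then costs nothing.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| ECG band | 0.5–40 | Hz | preserves P/QRS/T while removing wander and EMG; a 0.5–50 Hz variant is available via `filter_spec()` since both appear in common practice |
| normalization window | 10 | s | 10–15 beats at rest: stable statistics, still tracks activity transitions |
| σ_min clamp | 0.01 | input units | flat-line windows normalize to zero instead of exploding |
| STFT | L = 256, H = 64 | samples | 3.9 Hz resolution, 75% overlap |
| spectrogram floor ε | 1e-10 | — | silence maps to exactly −100 dB |
| beat window | 360 | samples | one cardiac cycle at 360 Hz |
| SNR training grid | 24, 12, 6 | dB | mild to severe corruption; the evaluation grid extends to 18, 0, −6 dB |
| accel coupling | 0.4·10^(−SNR/10) | m/s² RMS | heavier corruption ⇔ stronger motion; the exponent denominator is configurable (10 power-domain reading, 20 amplitude-domain) |
| motion classes | 0.1 / 0.3 / 0.6 | g (σ of magnitude) | Rest/Light/Moderate/Vigorous reporting rule; the auxiliary training labels instead use mean magnitude at 0.2 / 1.0 / 3.0 m/s² — both conventions are used in different roles, so both are implemented |
| τ, λ, λ_motion | 0.3, 0.1, 0.3 | — | gate-diversity threshold and loss weights |
| optimizer | Adam, lr 1e-4, batch 16 | — | full-scale defaults; the scaled demo uses lr 1e-3 (smaller model, very few epochs) |
| alarm policy | 0.5 g, 5 beats | — | motion-aware suppression threshold and persistence requirement; critical (VT-like) classes always pass |

## What the synthetic generator emulates — and what it does not

`synth_ecg_beat()` draws two morphology families: a P-QRS-T beat whose QRS
is a Ricker (Mexican-hat) pulse with spectral peak near 10 Hz, and a
PVC-like beat with at least twice the QRS duration, no P wave, randomized
polarity and a discordant T wave. Amplitudes and widths are jittered so the
families overlap but remain separable (a linear classifier on QRS width and
P-wave energy exceeds 95% accuracy — the learnability floor the training
tests rely on). `synth_record_set()` concatenates beats at a requested heart
rate with baseline drift; `synth_em_noise()` mixes 0.1–0.5 Hz wander with
burst-modulated 5–40 Hz noise and z-scores the result.

These fixtures give the pipeline ground truth and guaranteed separability;
they do **not** emulate rhythm-level structure (no AF irregularity), P/T
morphology pathology, multi-lead geometry, or real electrode mechanics.
Passing the toy-task tests therefore demonstrates that the machinery —
augmentation, gating, training, evaluation — behaves correctly, not that any
particular clinical accuracy would be attained on real archives.

## Numerical choices

* Zero-phase (forward–backward) filtering, so beat windows stay centered;
  the band edges are honored to within the doubled attenuation of the
  squared response.
* The spectrogram resize is align-corners bilinear interpolation (the resize
  method is otherwise unconstrained); global z-normalization uses
  ε = 1e-8 and maps constant inputs to zero.
* The dominant accelerometer frequency excludes the DC bin, which would
  otherwise win for any non-zero-mean magnitude signal.
* HRV uses the N−1 denominator under both the SDNN and RMSSD sums, and
  `pNN50 = 100/(N−1) · #(|ΔRR| > 50 ms)`, exactly as printed in the
  defining formulas.
* Noise mixing computes α from the *actual* noise slice drawn, so the
  empirical SNR of every augmented beat equals its tag to floating-point
  accuracy; the tested invariant is ±0.1 dB.
* σ_batch in the gate hinge is the N−1 sample standard deviation and carries
  gradient; at exactly constant gates the subgradient is taken as zero (the
  cross-entropy term breaks the symmetry after one step).
* McNemar uses the continuity correction with an exact binomial fallback
  below 25 discordant pairs; AUC groups tied scores on one threshold step,
  making the trapezoidal rule identical to the rank statistic.
* Report tables round half-away-from-zero to 2 decimals.
* Batch-norm layers fall back to running statistics whenever evaluated (or
  trained with a single sample), so single-beat inference cannot fail.
* Record splits use largest-remainder rounding of the 70/15/15 fractions
  with at least one record per partition (48 → 34/7/7, 3 → 1/1/1), and
  stratify by scoring 200 seeded shuffles on partition-level arrhythmia
  imbalance — the stratification procedure is otherwise unspecified, so a
  best-of-K search was chosen for determinism and simplicity.

## Design decisions taken where the design was open

* **Label schemes.** The binary Normal class includes the nodal and atrial
  escape beats (j, e) per the explicit table definition; a `strict_normal`
  flag restricts Normal to N, L, R for the narrower reading. The five-class
  grouping is implemented verbatim (including its clinically unusual VT
  group {F, /, f}).
* **Head depth.** The binary head is 640→256→2 with dropout 0.5; the
  five-class head inserts 256→128 with dropout 0.3 — the two sources that
  describe these heads each get their own configuration.
* **Accelerometer coupling exponent.** The magnitude law is read as
  `0.4·10^(−SNR/10)` (power-domain denominator, consistent with "inversely
  proportional" and with the mixing law); the amplitude-domain variant is a
  config switch.
* **HRV is computed and reported but not wired into the model input**: the
  encoder consumes only the spectrogram, and the feature tables list HRV as
  summary statistics. The functions are exported for users who want them as
  covariates.
* **Bayesian refinement ships disabled** (uniform prior, temperature 1.5
  default): no published activity-prior values exist, so it is exposed as a
  configurable post-hoc step with identity behavior by default.
* **Alarm re-arm.** After an alert fires, the persistence counter resets and
  a fresh consecutive run is required; the re-arm behavior is otherwise
  undefined.
* **Internal sampling rate** is 360 Hz throughout (the rate of the reference
  arrhythmia archive); sources that mention 1000 Hz acquisition are treated
  as upstream of the resample step.

## Scaled problem sizes

The package is pure R with no deep-learning runtime dependency: the network
layers (gather-based im2col convolutions, batch norm, BiLSTM with full
backpropagation through time, Adam) are implemented here and verified
against finite differences. The full-size architecture (224×224 input,
11.7M parameters) is built and shape-tested, but training-based tests and
the ablation use a scaled configuration of identical topology — 32×32
spectrograms, stage widths 8/16/32/64, 3×200 accelerometer segments (2 s at
100 Hz), 8 LSTM units per direction, lr 1e-3, 2 epochs, batch 16 — on the
standard toy task of 2000 fixture beats expanded 3× at 24/12/6 dB. At this
scale the gate-collapse ablation reproduces the qualitative result: with
λ = 0 the last-epoch median within-batch gate standard deviation sits near
0.04–0.07, with λ = 0.1 near 0.30, at equal (perfect) toy validation
accuracy.

## Known limitations

* Pure-R training is practical only at the demo scale; full-archive training
  is a GPU-scale exercise for which the same code paths apply unchanged.
* The WFDB reader covers single-segment headers with format 16/212 signals
  and MIT-format beat annotations — enough for the standard arrhythmia
  archive layout, not the full format zoo.
* The order-4 band-pass cannot provide 80 dB attenuation at 120 Hz from a
  360 Hz Nyquist of 180 Hz in its analog prototype sense; the measured
  zero-phase response attenuates a 120 Hz tone by far more than the 40 dB
  the tests assert, and the claim is recorded rather than asserted.
* Five-class training quality is limited by extreme minority-class scarcity;
  the published five-class class-weight vector does not follow the
  inverse-frequency rule and is therefore accepted as a user-supplied
  vector rather than derived.
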