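---
title: "Detecting post-ictal EEG suppression from two channels: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting post-ictal EEG suppression from two channels: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(pgesr)
library(dplyr)
```

## The problem

Post-ictal generalised EEG suppression (PGES) is the near-complete
flattening of the EEG — amplitudes below about 10 µV — that can follow a
generalised tonic–clonic seizure, beginning within 30 s of seizure end.
Long suppression (> 50 s) is one of the few established electrophysiological
markers of SUDEP risk, so detecting PGES and measuring how long it lasts is
clinically meaningful. Subcutaneous recorders make ultra-long-term
monitoring practical but provide only two channels, far less spatial
context than the 8–10 scalp channels used by earlier PGES detectors.

`pgesr` treats the problem as **anomaly detection**: most of a recording is
ordinary background EEG; suppressed epochs are rare outliers. A small
variational auto-encoder (VAE) learns to reconstruct background epochs;
epochs it reconstructs poorly are flagged as suppression. Temporal
smoothing and run-length analysis then convert epoch flags into a duration
estimate per patient.

## Pipeline and parameters

| Stage | Parameter | Default | Why |
|---|---|---|---|
| montage | anodes − reference | FP2−F8, T8−F8 | the scalp channels closest to a subcutaneous implant |
| resample | target rate | 207 Hz | operating rate of the two-channel device |
| band-pass | pass band, order | 0.5–45 Hz, 8th-order Butterworth | retains the δ–β range the features use; removes drift and EMG-range energy |
| notch | centre, Q | 50 Hz, 30 | mains interference; Q = 30 keeps frequencies ≥ 5 Hz away within 1 dB |
| epochs | window, hop | 5 s, 2.5 s | enough samples for a stable Welch PSD while resolving ~27 s events |
| label rule | overlap fraction | 0.5 | an epoch is "suppressed" when at least half of it overlaps the annotation |
| VAE | layers, latent | 14–14–2–14–14 | one hidden layer per coder at the feature width; 2-d latent |
| training | lr, batch, epochs | 10⁻⁴, 64, 100 | small, stable steps for a 522-parameter model |
| smoothing | window, step | 10 s (4 epochs), 1 epoch | repairs isolated misclassifications inside runs |

Seizure segments are **excised before preprocessing** using their
annotations, and the excision records splice points so that no epoch is
ever cut across two non-contiguous pieces of signal. Annotations are kept
in seconds and re-timed exactly (sample-index arithmetic) to the spliced
timeline.

### Filtering

Zero-phase (forward–backward) filtering is used everywhere so that epoch
labels are not shifted in time against the annotations; the stated filter
order refers to the band-pass design before this doubling. At 207 Hz with a
0.5 Hz lower edge, the 16-pole band-pass is numerically singular in
transfer-function form, so the filter is built as a cascade of second-order
sections obtained from the analog Butterworth prototype (band-pass
transform, then bilinear transform), each section started from its
steady-state response to the first sample. The chain satisfies, by test:
≤ 1 dB deviation at 10 Hz, ≥ 20 dB rejection at 50 Hz, and a 100 µV
constant input leaves < 1 µV RMS.

Resampling from archival rates (e.g. 1024 Hz) to 207 Hz is Fourier-domain
spectrum truncation — an ideal anti-aliasing low-pass for band-limited
signals — after removing the line through the endpoints to avoid
wrap-around ringing. Amplitude fidelity in the pass band is ~0.01%.

### Features

Each (channel, epoch) yields 14 features, in fixed order: mean, SD, median,
maximum and minimum of the rectified signal |x|; absolute band power in
δ/θ/α/β; the same four as fractions of their sum; and the Petrosian fractal
dimension. Choices worth noting:

* The time statistics are computed on |x| (the rectified signal). Computing
  them on x and then taking absolute values would lose the amplitude
  information that distinguishes suppression.
* The PSD is estimated by Welch's method with 1 s Hann segments and 50%
  overlap — a standard robust estimator at 5 s windows — and integrated
  over each band by the trapezoidal rule.
* Relative powers are normalised by the **sum of the four band powers**
  rather than total spectral power. This gives the exact sum-to-one
  invariant the tests rely on, and the four bands jointly cover the
  0.5–40 Hz pass band anyway.
* Petrosian's dimension uses the sign changes of the first difference
  (`N_δ`); flat runs inside a window contribute no sign changes. A monotone
  window gives exactly 1.

Min–max scaling is learned on the training split only and applied
everywhere with clipping to [0, 1], so test values outside the training
range stay inside the valid domain of the binary-cross-entropy loss. A
feature constant in training maps to 0.

### The anomaly score

Training minimises the usual VAE objective — BCE summed over the 14
features plus the analytic KL divergence to the standard-normal prior —
with Adam, everything seeded: initialisation, per-epoch shuffling, latent
draws. Two identical calls produce bit-identical fits.

Scoring is deterministic: a row is encoded to its latent mean μ(x) (no
sampling), decoded, and scored by the **excess BCE**

$$s(x) \;=\; \tfrac{1}{14}\sum_{j} \Big[\mathrm{BCE}(x_j, \hat x_j) - \mathrm{BCE}(x_j, x_j)\Big],$$

i.e. the mean binary KL divergence between each target value and its
reconstruction. Raw BCE is bounded below by the entropy of the row itself,
and that bound varies strongly across rows: a background epoch whose scaled
features sit mid-range carries an entropy floor of ~0.6 nats/feature, while
a suppressed epoch (features clipped near 0) has a floor near 0. With raw
BCE as the score, the floor term dominates and background can outscore
suppression even when the model reconstructs background perfectly.
Subtracting the per-row floor removes exactly that artefact: the score is 0
iff the reconstruction is perfect and measures only reconstruction
failure, so the direction "suppression scores higher" follows from the
model being trained on background. On the default synthetic cohort this
score separates the classes cleanly (validation F1 ≈ 0.96–0.98 across
seeds), where raw BCE inverts the classes.

The decision threshold is **calibrated, not fixed**: an exhaustive scan
over all midpoints between consecutive sorted unique validation scores,
maximising F1 for the suppression class, ties broken toward the lower
threshold (higher recall). Published absolute thresholds only transfer
between identically normalised scores, so the calibration is the operative
mechanism and any shipped constant is just a recorded instance.

### Smoothing and durations

Epoch predictions are smoothed by a sliding window of 4 epochs (10 s)
moving one epoch at a time, modifying the sequence in place so later
windows see earlier repairs. A window is only eligible when its last
element differs from the first element outside it — a boundary — and the
test is applied symmetrically to 0→1 and 1→0 boundaries, because a
one-sided rule could not repair positive runs broken by spurious zeros,
which is the stated purpose of the step. Within an eligible window a strict
majority flips the minority; exact 2–2 ties are left unchanged since both
values then hold "50% or more" and no majority exists. The final window,
having no outside element, is skipped. An independent brute-force
implementation agrees on all 4096 binary sequences of length 12.

The predicted duration of a session/channel sequence is the **longest run
of positive epochs × 2.5 s**. The longest-run reading also explains how a
session with no true suppression can still receive a small positive
duration (a short spurious run), which is exactly the behaviour seen in
per-patient tables where a patient with true duration 0 s is assigned 5 s.
Durations are averaged over all sessions and channels of a patient, and
the **offset** is the absolute difference from the annotated truth. The
cohort average offset is the arithmetic mean of the per-patient offsets
(sum ÷ number of rows).

## The synthetic cohort

The generator emulates the structure of the clinical material, not its
microstructure:

* two channels at 207 Hz sharing a common component (weight 0.6), so they
  correlate like neighbouring electrodes;
* background: band-limited (0.5–45 Hz) 1/f-shaped noise at 35 µV RMS with
  an optional 10 Hz rhythm (fraction 0.3) — amplitudes of tens of µV are
  typical adult background EEG; the published material reports no
  amplitude statistics, so these are engineering choices exposed in
  `synthetic_config()`;
* suppression: the same process scaled to 2 µV RMS (comfortably below the
  10 µV criterion), duration drawn from N(27.1, 2.6²) s truncated at 1 s —
  the annotated distribution of the clinical cohort — starting uniformly
  within 30 s of seizure end, with 1 s raised-cosine tapers;
* an annotated seizure segment of high-amplitude noise whose content is
  irrelevant by construction, because it is excised before analysis;
* per-patient lognormal amplitude factors (sd 0.15), 26 patients split
  10/7/9 by patient, and a background-heavy training composition: only
  about half of the training sessions contain suppression at the default
  20:1 background:PGES epoch-ratio target, while validation and test
  sessions always do (calibration and evaluation need both classes).

What the simulator does **not** model: real seizure morphology, artifact
taxonomies (EMG bursts, electrode pops, movement), non-stationary
background, other suppression-like modalities, or inter-channel
asymmetries. Passing the synthetic experiment therefore demonstrates that
the pipeline's machinery is correct and that the method works at a clean
~17× amplitude contrast; it does not certify clinical performance, where
contrast is lower and artifacts mimic suppression. The zero-contrast
negative control (suppression RMS = background RMS) closes the loop from
the other side: there the score distributions overlap and epoch
predictions become label-independent, confirming that the positive result
is driven by the amplitude contrast and not by leakage.

## Numerical choices and degenerate inputs

* Reconstructions are clamped to [10⁻⁷, 1 − 10⁻⁷] inside the loss, so the
  loss is finite even at saturated targets; log-variances are clamped to
  ±15 before exponentiation.
* `select_threshold` on an all-identical score set returns that value with
  a warning; `classify` is strict (`score > threshold`), so a score exactly
  at the threshold is background.
* Epochs shorter than one window produce an empty table with a warning;
  excising an interval that covers the whole recording is an error.
* Overlapping annotation intervals of the same label are merged before
  excision; interval arithmetic is half-open `[start, end)` in seconds,
  with sample-exact splicing.
* EDF writing truncates to whole 1 s records (with a warning) because EDF
  stores complete records; the tabular format has no such restriction.

## Problem sizes

The default experiment — 26 patients × 2 sessions of roughly 170 s each,
about 10,000 epoch rows, a 522-parameter VAE for 100 epochs — runs in
tens of seconds on one CPU core. The test suite uses the same defaults for
the end-to-end checks and smaller cohorts (6–12 patients, single sessions)
for plumbing tests; the learning-curve and negative-control experiments
use reduced cohorts for the same reason. These sizes are the package's
own test design; `synthetic_config()` scales all of them.

## Known limitations

* The score scale depends on the scaled feature distribution, so
  thresholds are not portable across feature sets or scalers —
  recalibrate per training run.
* Duration resolution is one epoch hop (2.5 s); sub-hop accuracy is not
  attainable by construction.
* The smoother repairs isolated errors inside runs but cannot recover
  events whose every epoch was missed, and it can slightly lengthen runs
  at their boundaries.
* Patient-level averaging assumes each session's annotation is one global
  suppression interval shared by both channels; per-channel annotations
  would need a wider duration table.

```{r example, eval = FALSE}
# the full default experiment
res <- run_pges_experiment()
res$detection_rate
res$durations
glance(res$metrics)
autoplot(res$model$fit)
```
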