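---
title: "Methods: acoustic features and the grouped-support-vector network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic features and the grouped-support-vector network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryclass)
```

## The problem

Neonates communicate need states — hunger, sleepiness, discomfort — through
cries whose fundamental frequency sits in the 250–600 Hz band, well above
adult speech. `cryclass` implements a complete pipeline for classifying
labeled cry recordings into those three classes: preprocessing, a
twelve-family acoustic feature representation, random-forest variable
selection, and a boosted committee of RBF-kernel support-vector classifiers
("grouped-support-vector network") evaluated by stratified k-fold
cross-validation. Because clinical cry recordings are not generally
redistributable, the package also ships a seeded source–filter generator of
synthetic cry-like audio so that every stage is testable offline.

## Preprocessing

Seven steps turn a WAV file into analysis-ready spectra:

1. **Peak normalization** — samples divided by the maximum absolute
   amplitude, making energy thresholds comparable across recordings.
2. **Cry-unit detection** (subsuming end-point detection) — cries alternate
   voiced expiratory bursts with near-silent inspiration. We use a
   double-threshold detector on short-time frame energy with a
   zero-crossing-rate guard: frames with energy ≥ 10% of the clip maximum
   seed a unit, which extends over contiguous frames with energy ≥ 2% of
   the maximum and ZCR ≤ 0.5; units closer than 50 ms merge, units shorter
   than 100 ms are dropped. Frame-level decisions overshoot by up to one
   frame, so unit boundaries are refined to sample precision by trimming to
   where the 5 ms RMS envelope stays above 12% of the unit peak. Detection
   runs on the un-pre-emphasized signal, where energy contrasts are most
   stable.
3. **Pre-emphasis** — y[n] = x[n] − 0.97·x[n−1], applied per unit, to
   flatten the spectral tilt before spectral analysis.
4. **Framing** — N = 1024 samples with 50% overlap (hop 512); ~23 ms at
   44.1 kHz, 64 ms at the 16 kHz test scale. Trailing partial frames are
   dropped rather than zero-padded, avoiding padding bias in frame
   statistics.
5. **Hamming windowing** — w[n] = 0.54 − 0.46·cos(2πn/(N−1)).
6. **FFT** — magnitudes of bins 0..N/2 are retained.

All thresholds and sizes are `feature_config()` arguments.

## The twelve feature families

Per cry-unit frame we compute, in the time domain: **magnitude**
(sum of absolute amplitudes), **average** (signed
mean), **variance** (population variance, divisor N), and **zero-crossing
rate** (fraction of adjacent sample pairs with differing sign, zeros
inheriting the preceding sign — the conventional definition of the rate of
sign change).

In the frequency domain: **bandwidth**, the power-weighted spread
Σ|S(i)|²(i−FC)²/Σ|S(i)|² about the power-weighted centroid FC, kept in
squared bin units (no square root); **peak** and **valley**, the natural
log of the mean of the top (respectively bottom) ⌈α·n⌉ magnitudes of each
of four logarithmically spaced subbands (α = 0.2; at 44.1 kHz the default
bands are roughly 0–0.7, 0.7–2.8, 2.8–11, 11–22 kHz), with logs floored at
ln 10⁻¹⁰; **pitch**, by normalized autocorrelation over a dedicated
4096-sample window centered on the frame — an ordinary 1024-sample frame
holds fewer than six periods at 250 Hz — searched over the 250–600 Hz cry
band with a 0.3 voicing gate, the integer-lag peak refined by parabolic
interpolation (lag quantization alone costs up to ~1.3% at 16 kHz, more
than the accuracy we require of the estimator); **formants** F1–F6 by
LPC root-finding (order 18, autocorrelation/Levinson–Durbin method,
bandwidth cutoff 700 Hz, ascending, zero-padded when fewer are found);
**LPCC**, 12 cepstral coefficients from the order-12 LPC fit via the
standard recursion c_m = a_m + Σ (k/m)c_k a_{m−k}; **MFCC**, 12
coefficients of the orthonormal DCT-II of log energies from a 26-filter
triangular mel filterbank (HTK mel scale, 0 Hz–Nyquist) applied to the
power spectrum, coefficient 0 excluded; and **ΔMFCC**, the regression
delta over a ±2-frame window with replicated edges.

The classification unit is configurable: the default aggregates frames to
one row per clip (per-dimension mean and standard deviation, 112 columns),
matching how a caregiver-facing system would label whole cries; a
frame-level mode with margin-weighted clip voting (`predict_clip()`) is
also provided, since either unit is defensible.

## Variable selection

`select_variables()` is a two-step, random-forest procedure in the spirit
of VSURF. Step 1 ranks feature *families* (all 12 MFCC dimensions count as
one family, and so on — selection outcomes are most interpretable at the
family level) by mean out-of-bag permutation importance, averaged over
`n_repeats` forests of `ntree` trees (default 2000), each fit with one
row-permuted "decoy" copy of every column. Families are eliminated unless
their importance exceeds the decoy mean plus two decoy standard
deviations; the decoy mean alone is not a usable null threshold, because
under the null real columns and decoys are exchangeable and half of pure
noise would survive. Step 2 fits nested forests on the top-1, top-2, …
surviving families and keeps the smallest prefix whose OOB error is within
one standard error of the minimum; the OOB error of each subset is
averaged over several forests because a single forest's OOB estimate is
noisy at the one-standard-error resolution. Per-dimension selection is
available via `per_family = FALSE`.

## The grouped-support-vector network

The classifier is a committee (default 300 members) of multiclass
RBF-kernel SVMs (one-vs-one decomposition, as in `e1071`). A single
(C, γ) pair is chosen once by stratified cross-validated grid search over
C ∈ {1, 3, 33} and γ ∈ {0.1, 0.2, …, 5.0}, ties broken toward smaller C
then smaller γ, and shared by all members. Features are z-scored with
training statistics before fitting — RBF kernels are scale-sensitive.

Members are trained with SAMME-style multiclass boosting. Sample weights
start uniform; each round draws a weight-proportional bootstrap resample
of the training set, splits it 80:20 (stratified) into fit and validation
parts, fits the SVM, and computes the weighted validation error ε. The
member's vote weight is ln((1−ε)/ε) + ln(K−1) (K = 3 classes), floored at
0 and capped at ln 10⁶ when ε = 0; training rows the member misclassifies
are upweighted by e^(vote weight) and the weights renormalized. Members no
better than chance (ε ≥ (K−1)/K) receive weight 0 and reset the weights to
uniform, as does a weight distribution so degenerate that no valid
resample can be drawn. Prediction is weighted majority voting: each row's
class scores are the summed vote weights of members predicting that class,
normalized to sum to one (usable as ROC scores); ties break by class
order. A plain bagging mode (`mode = "bag"`: uniform resampling,
accuracy-proportional vote weights) is kept for ablation.

With one member the committee provably reduces to its base SVM, which the
tests exploit as a contract.

## Evaluation

`confusion_matrix()` uses rows = actual, columns = predicted. Per-class
accuracy is the diagonal over the row sum; the **mean accuracy is the
unweighted mean of the per-class accuracies**, not the pooled accuracy —
the two differ whenever classes are imbalanced, and the reference results
this package reproduces are only consistent with the unweighted reading.
Reported accuracies are truncated (not rounded) to four decimals
(`truncate4()`; 113/129 = 0.87596 reports as 0.8759), again matching the
reference tables; full precision is kept internally. `kfold_cv()` wraps
the *whole ensemble* in stratified 10-fold cross-validation — every row
validates exactly once — and aggregates out-of-fold predictions into one
confusion matrix, one-vs-rest ROC curves with trapezoidal AUC, and an
optional per-group (infant sex) report.

## The synthetic cry generator

`generate_clip()` uses source–filter synthesis: a glottal-like impulse
train at a class-conditional F0 (drawn uniformly from the class's band,
with 2% vibrato at 5 Hz), passed through two cascaded one-pole low-pass
filters (coefficient 0.95) that impose the steep spectral tilt of a real
glottal source — without it the waveform is dominated by the highest
formant and its zero-crossing rate no longer resembles voiced audio —
then through the class's three two-pole formant resonators (150 Hz
bandwidth), shaped by a burst/pause envelope with 10 ms raised-cosine
ramps (pauses emulate inspiration and exercise end-point detection), plus
white noise at 20 dB SNR.

The class acoustics are fictional: no class-conditional acoustic
statistics are available for real hunger/sleep/discomfort cries, so the
presets parameterize *separability* instead of claiming realism. The
`separable` preset gives the classes disjoint F0 bands (hunger 420–480,
sleep 280–330, discomfort 520–580 Hz) and distinct formants; the
`overlapping` preset gives identical F0 bands and formants differing by
3%, degrading classification toward chance; `noiseless` removes noise and
pauses for exact end-point ground truth. Defaults are 2 s clips at 16 kHz,
a scale at which the full pipeline (120 clips, 50 members, 10-fold CV)
runs in well under a minute; the study-scale 44.1 kHz / 10–60 s
configuration is supported. Consequently, passing tests demonstrate that
the pipeline recovers *constructed* class structure from raw audio — they
cannot certify accuracy on real hospital recordings, which differ in
noise, channel, and within-class variability.

## Numerical and design notes

* The magnitude feature is the absolute sum Σ|S(i)| — how far the samples
  lie from zero regardless of sign; a signed sum would cancel to near zero
  on any zero-mean frame. The conventional sign-change definition is used
  for ZCR.
* The bandwidth centroid FC is the power-weighted spectral centroid in bin
  units; peak/valley operate on magnitudes sorted within the subband
  (the two features then walk the same sorted array from opposite ends),
  with natural logs.
* Zero-energy frames yield zero formants/LPCC with a warning rather than
  an error; all-zero spectra yield bandwidth 0 with a warning; unvoiced
  pitch encodes as 0; absent formants as 0 — feature matrices never
  contain missing values.
* Selection runs once on the full dataset before cross-validation by
  default, mirroring the protocol under which the reference confusion
  matrices were produced; this leaks selection information across folds,
  and `run_config(selection_in_fold = TRUE)` requests the unbiased
  variant.
* Grid values C ∈ {1, 3, 33} are taken as a literal set; the γ grid as a
  0.1-step sequence to 5.0. Note that γ of that order suits the reduced
  (post-selection) feature set; on the full 112-dimensional standardized
  representation even γ = 0.1 pushes all RBF distances into the kernel
  tail.
* Boosting uses weighted *sample* reweighting plus weighted majority
  voting. Gradient-boosted trees are deliberately not the final
  classifier; the boosting vocabulary here means the SAMME-style
  reweighting scheme around SVM members.
* Determinism: every stochastic step (fold assignment, resampling,
  forests, generators) is seeded from the caller's seed; identical input
  and seed reproduce models, predictions, and reports exactly.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` use 2 s clips at 16 kHz, 40
clips per class for the end-to-end runs, 50 committee members, 10-fold
CV, forests of 300–500 trees for the selection simulations, 100 tones for
pitch recovery, and 20 seeded repetitions for selection recovery. These
sizes were chosen as the smallest at which the measured properties are
stable; the package defaults (300 members, ntree = 2000) remain the
recommended analysis configuration.

## Known limitations

* The cry-unit detector is amplitude-based; it will fuse overlapping
  speech/noise events with cries and has no spectral noise reduction
  beyond silence trimming.
* Formant tracking by LPC root-finding is unreliable for high-pitched
  sources (harmonic spacing comparable to formant spacing) — a known
  limitation of LPC on infant vocalizations; formant features accordingly
  rank low on the synthetic data.
* The gender comparison is a reporting facility; the generator assigns
  sex tags round-robin and gives them no acoustic correlate.
* WAV reading covers uncompressed RIFF PCM (8/16/24/32-bit int, 32-bit
  float); compressed or streamed formats are out of scope.
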