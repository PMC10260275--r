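---
title: "Sleep-oscillation lateralization and emotional recognition memory: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep-oscillation lateralization and emotional recognition memory: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlelat)
```

## The scientific problem

Overnight memory consolidation is tied to specific sleep oscillations:
fast sleep spindles (13–16 Hz) and slow oscillations (SOs, ~0.2–1.25 Hz)
in NREM sleep, and theta activity (4–7 Hz) in REM sleep. Because
emotional processing is hemispherically asymmetric, a natural question is
whether the *lateralization* of these oscillations — how much stronger
they are over the right frontal cortex than the left — predicts whether
neutral or emotional material is preferentially remembered.

`spindlelat` implements the full analysis chain for such a study: event
detection in polysomnography (PSG), coupling-phase metrics, standardized
REM theta power, right-vs-left lateralization indices, signal-detection
scoring of a three-retrieval picture-recognition task, and the
repeated-measures models linking oscillatory covariates to memory. A
synthetic-data generator emulates every input with known ground truth, so
each stage is validated end to end.

## Preprocessing

EEG is band-passed 0.2–35 Hz with a Hamming-windowed sinc FIR whose
−6 dB (half-amplitude) points sit half a transition width outside the
passband (0.1 and 35.1 Hz with the default 0.2 Hz transitions). The
kernel is computed directly as the ideal band-pass impulse response times
a Hamming window, applied once by FFT convolution, and the symmetric
kernel's group delay is discarded — a genuinely zero-phase response
without squaring the magnitude (the cost of the usual forward–backward
trick). The filter order follows the Hamming design rule
`order = 3.3 * rate / transition` (4224 at 256 Hz) unless given
explicitly.

Signals are re-referenced to the linked mastoids, `x - (A1 + A2)/2`.
Epochs are 30 s; an epoch is analyzed iff its stage is wanted (N2 and N3
are pooled as NREM for all event detection) and its summed artifact
overlap is at most 8 s. Whether the 8-s rule refers to one artifact or
the per-epoch sum is ambiguous in common practice; the sum is the default
(`epoch.artifact_rule = "sum"`), a single-interval variant is available.
Electrode impedance is hardware metadata absent from EDF, so the
impedance exclusion rule is exposed as a per-epoch flag argument
(default: all pass). Spindle density divides event counts by included
minutes *without* subtracting sub-epoch artifact time — events inside
artifact segments are discarded instead; an artifact-corrected
denominator sits behind `density.artifact_corrected`.

## Spindle detection

Detection operates on the rectified 13–16 Hz band-passed trace (order
2816 at 256 Hz, scaled proportionally for other rates). The channel's
mean rectified amplitude over artifact-free NREM defines two thresholds:
upper = 5× mean (peak criterion) and lower = 2× mean (extent criterion).

A literal reading of "stay above the lower threshold continuously for
250 ms on each side of the peak" is impossible on a rectified trace: it
crosses zero twice per oscillation cycle (~every 34 ms at 14.5 Hz). The
minimum inter-spindle gap — 78.1 ms, about one 13 Hz period — resolves
this: sub-lower dips *shorter* than the gap are bridged, which both keeps
a burst's half-cycle dips from fragmenting it and absorbs a closely
following burst into the earlier event (the larger maximum becomes the
peak). On the bridged segments the detector then requires: rectified
maximum above the upper threshold (first sample wins plateau ties),
≥250 ms above-lower on each side of the peak (hence the 0.5 s minimum
duration), duration ≤3 s, peak amplitude ≤200 µV (the only absolute
criterion — everything else is scale-invariant), and no overlap with
excluded epochs or artifact segments (strictest reading: any excluded
sample drops the event).

An envelope variant (`spindle.amplitude = "envelope"`, Hilbert magnitude)
is available; the rectified trace is the default because the
mean-amplitude thresholding tradition this detector descends from
operates on the rectified filtered signal.

## Slow oscillations and coupling

SO detection runs on the 3.5 Hz low-passed trace in two passes. Pass 1
collects candidate cycles: intervals between consecutive
positive-to-negative zero crossings with duration 0.8–5 s (equivalently
0.2–1.25 Hz) lying wholly inside artifact-free NREM, recording each
cycle's most negative and most positive excursion. Pass 2 keeps cycles
whose negative peak is strictly below the candidate-mean negative peak
*and* whose peak-to-peak amplitude strictly exceeds the candidate-mean
peak-to-peak, with means computed per channel per night over
duration-valid candidates only. "Strictly" is implemented with a 1e-8
relative tolerance so that numerically identical cycles (a pure sinusoid
after FFT filtering) never pass.

Coupling phase uses a different trace than cycle geometry, mirroring how
the two operations are defined: the signal is band-passed 0.2–1.25 Hz,
Hilbert-transformed, and the instantaneous phase read at each spindle's
amplitude peak, for spindles whose peak falls within an SO's
zero-crossing span (cycles are disjoint, so the pairing is unique). The
convention places the positive SO peak at phase 0, the falling zero
crossing at +π/2 and the trough at ±π; it is locked by a unit test on a
pure cosine. Coupling distance is |phase| ∈ [0, π]; summaries report the
arithmetic mean distance, the circular mean phase (atan2 of mean sine and
cosine) and the standard Rayleigh-test approximation
`p = exp(sqrt(1 + 4n + 4(n² − R²)) − (1 + 2n))`. An empty pair set
propagates as missing, never as zero.

## REM spectral analysis

Per included REM epoch, Welch PSD with 1024-sample Hamming segments at
50% overlap (segment means removed), one-sided, in dB (10·log10 of
µV²/Hz). Six band means (delta 0.5–4, theta 4–7, alpha 8–12, sigma
12–16, beta1 16–22, beta2 22–30 Hz) are taken over bins whose center
lies in [low, high), then averaged across epochs, giving a 12-cell table
(2 frontal channels × 6 bands). The two theta cells are z-scored against
the mean and *sample* SD of the 12 cells — removing inter-individual
amplitude differences (skull, electrode conductance) while preserving the
F3/F4 contrast — and REM theta is the mean of the two z-scores.
Band-averaging precedes standardization (one value per channel per band);
population-SD standardization would differ only by a constant factor
absorbed partially, not fully, by the lateralization ratio, which is why
the choice is documented here. Epochs shorter than one segment are
skipped.

## Memory scoring

Each of three retrievals (immediate, 12 h, 24 h) shows 50 encoded targets
and 50 unseen foils, 25 neutral / 25 emotional within each set — 150
encoded pictures plus 150 distinct foils, 300 stimuli in total. Responses
are recollected / familiar / new (button codes 1/2/0 are mapped at
ingest). Total hit rate counts recollected-or-familiar to targets;
false-alarm rate the same to foils; recollection-based scoring counts
only "recollected". Discriminability is `d' = z(hit) − z(fa)`. With 25
trials per cell perfect rates are common, so an extreme-rate rule is
mandatory: rates of 0 and 1 are replaced by `1/(2n)` and `1 − 1/(2n)`
(default), with the log-linear (+0.5) correction available behind
`dprime.correction`. Difference scores (retention deltas between
consecutive retrievals; neutral − emotional per retrieval and pooled) are
exact cell arithmetic.

## Statistics

*Lateralization index*: `(right − left) / ((right + left)/2)` — positive
means right-dominant; antisymmetric and scale-invariant. When the
denominator magnitude falls below a guard threshold the index is returned
as missing, never infinite; the guard matters mainly for theta, whose
denominator is a mean of two z-scores and can approach zero.

*Two-way RM-ANOVA* (retrieval time × emotion on d') uses `stats::aov`
with the subject error strata; no sphericity correction is applied by
default, matching the convention of reporting uncorrected dfs such as
F(2, 62) at n = 32. Degenerate all-constant input short-circuits to
F = 0. Bonferroni-corrected paired t-tests follow up time (on
emotion-pooled d') and emotion within each retrieval. The test suite
checks the engine against a from-scratch sums-of-squares oracle on random
4×3×2 data to 1e-8.

*RM-ANCOVA with a continuous oscillatory covariate* is authored here as
within-subject contrast regression: the six d' cells are projected onto
orthonormal contrasts (mean, time, emotion, time × emotion); each
contrast set is regressed on the mean-centered covariate plus controls —
sex, measurement location, sleep duration (Model 1), plus ln(x+1) BDI and
GAD-7 with missing questionnaire scores mean-imputed (Model 2); and the
covariate's extra sum of squares is pooled across contrast columns,
giving the averaged univariate F with df1 = k, df2 = k(n − p). For 1-df
effects this equals the squared t of the corresponding contrast
regression (asserted numerically); for n = 32 with Model 1 controls the
dfs reproduce the familiar F(1, 27) / F(2, 54) bookkeeping. The ln(x+1)
questionnaire transform is chosen because the scales start at 0. The
covariate is mean-centered; an ill-conditioned or rank-deficient design
raises a diagnostics error naming the offending columns. Covariate models
are reported unadjusted — Bonferroni is applied only to the pairwise
post-hocs.

*Follow-up regressions* are OLS of a difference score on the predictor
plus the same controls, adding the previous retrieval's matching
difference score when a later-retrieval delta is examined (isolating the
between-retrieval change). *Preliminary screens* provide one-way ANOVAs
over sex/location, Pearson correlations, a chi-squared recruitment ×
location test, and |z| > 3 outlier flags; constant variables yield
missing values rather than errors.

## The synthetic-data generator

The generator's defaults are the study conditions: 32 subjects, 256 Hz,
six-channel montage (F3, F4, C3, C4, A1, A2), stage architecture near
N2 36% / N3 24% / REM 18% / N1 6% (realized fractions within ±0.03 by
construction), pink (1/f) background at 15 µV RMS with quieter mastoids,
3.3 spindles/min, 4 SOs/min at ~150 µV peak-to-peak, 70% of spindles
phase-locked near the SO positive peak (mean phase ≈ −2°, concentration
chosen so the mean coupling distance is ≈0.95 rad), REM theta as
band-limited 4–7 Hz activity at 7 µV RMS, and 5% of sleep epochs
carrying 1–12 s artifacts. Nights default to a reduced 60 min;
`night_min = 480` gives a full night. Memory follows an equal-variance
signal-detection model (targets N(d, 1), foils N(0, 1), dual criteria
for recollected/familiar); target strengths decline over retrievals from
≈2.6, and the 24-h emotional deficit is produced by a criterion shift
for emotional foils only — inflating emotional false alarms while
leaving hit rates untouched, the pattern the analysis should recover.

Three design points deserve emphasis:

* **Spindle amplitude is parameterized in threshold units.** Burst
  amplitude is `amp_factor` × the channel background's rectified
  spindle-band mean; since the upper detection threshold is ≈5× that
  mean, the default factor 20 places injections at roughly 2.5× the
  upper threshold, and recall curves are interpretable in detector
  units.
* **SOs are injected as a 3-cycle Hann-tapered wave** whose
  full-amplitude central cycle is the slow oscillation proper. An
  isolated single cycle will not do: after 0.2–1.25 Hz filtering its
  Hilbert phase advances only ~5.3 rad over the cycle, so phases near
  +π/2 are never realized and phase-targeted injection is biased by up
  to ~0.3 rad. The flanks keep the filtered signal locally oscillatory;
  coupled spindles are then placed by looking up the target phase in the
  *measured* phase profile of the filtered template, and recovery of
  injected phases −π/2, 0, +π/2, π is accurate to <0.05 rad.
* **REM theta spans the whole band.** A single tone occupies ~1 of 24
  theta-band bins, so a hemispheric amplitude ratio is diluted ~24-fold
  in the dB band mean; band-limited Gaussian theta keeps the asymmetry
  detectable at the spec'd ratio (1.3).

Hemispheric asymmetries are subject-level latent values (spindle rate,
coupling-distance target, theta amplitude; SD 0.25 each) applied
multiplicatively per hemisphere; coupling-distance targets are converted
to von Mises concentrations by numerically inverting E|φ|(κ). Effect
wiring ties the latent coupling lateralization to the neutral−emotional
strength difference with weight −0.8 (right-lateralized coupling distance
→ smaller neutral benefit), and spindle lateralization to the 24-h
emotional difference with weight +0.8. Setting both weights to 0 gives
the null generator used for type-I calibration.

What the generator does *not* emulate: biophysical source geometry,
stage-transition dynamics, spindle frequency drift, correlated
inter-channel noise, or real artifact morphology. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under a
controlled model of the data, not performance on clinical recordings.

## Numerical choices and problem sizes

Ground-truth event lists are emitted independently of any detector, so
recall/precision and phase-recovery metrics are well defined. Identical
spec and seed reproduce outputs exactly. Time is seconds from recording
start with half-open event intervals [start, end); sample i covers
[(i−1)/rate, i/rate).

The validation suite runs at sizes chosen for a laptop-class single CPU:
detector recovery on one 20-min two-channel night; phase recovery on
45-min single-channel nights (≥200 phase-locked spindles per phase);
type-I calibration with 500 score-level replicates of n = 32 (the
score-level generator draws hit/false-alarm counts binomially under the
same signal-detection model — statistically identical to scoring full
response tables); and end-to-end wiring recovery over 10 cohort
replicates of 32 subjects with 15-min nights analyzed on the frontal
pair. EDF I/O quantizes to 16 bits against a per-channel symmetric
physical range, so round trips are exact to one quantization step.

## Known limitations

Lateralization indices estimated from short nights are noisy (tens of
coupling pairs per channel), attenuating covariate effects toward zero in
end-to-end runs; full-length nights reduce this. The Rayleigh p-value
approximation is the standard large-n form. The contrast-regression
ANCOVA reproduces the averaged-univariate F; it does not implement
sphericity-corrected or multivariate test variants. Handedness is carried
as a covariate column (with a distinct imputed category for missing
values) for sensitivity reruns but no automated sensitivity battery is
provided.
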