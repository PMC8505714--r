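---
title: "Decoding reach-and-grasp movements from movement-related cortical potentials"
author: "mrcpgrasp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding reach-and-grasp movements from movement-related cortical potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcpgrasp)
```

## The problem

When a person executes a voluntary hand movement, a slow negative
deflection — the movement-related cortical potential (MRCP), dominated by
the Bereitschaftspotential — builds up over the central motor cortex in
the second before the movement and resolves during its execution. Its
low-frequency (0.3–3 Hz) time-domain amplitude carries enough information
to tell *which* movement was performed. This package implements a
complete single-trial analysis chain for a six-condition reach-and-grasp
paradigm (palmar, pinch, push, twist, plug, and a no-movement control):
preprocessing, artifact rejection, behavioral timing, grand-average MRCP
statistics, and sliding-window shrinkage-LDA decoding with principled
chance bounds. Because no public recording of this paradigm exists, the
package also ships a paradigm-faithful synthetic EEG generator with known
ground truth, so every stage is testable at desk scale.

## The paradigm emulated by the generator

A subject completes `n_sessions` sessions of 60 trials (10 per condition,
randomized within session). Each 10-s trial starts with a beep at 0 s, an
auditory target cue at 3 s names the condition, and a "Go" cue at 5 s
releases the movement. The default configuration (8 sessions) yields 480
trials per subject, 80 per condition. EEG is recorded from a 40-channel
fronto-parietal 10–20 montage at 1,000 Hz; a pressure button under the
resting hand opens at hand-lift (defining the true movement onset = Go +
reaction time) and a force transducer on the grasped object traces the
grasp itself.

The generator (`simulate_subject()`) superimposes:

* **MRCP templates** (`mrcp_templates()`): a piecewise-linear negative
  ramp shared by all grasp conditions, starting 0.5 s before the true
  onset and peaking (−8 µV by default at the spatial maximum) exactly at
  onset, followed by a condition-specific recovery and a Gaussian rebound
  bump. Push and plug carry a large (+6 µV) rebound near 1.2 s and are
  generated with *identical* post-onset shape — they are intentionally
  confusable, mirroring the near-indistinguishable push/plug contrast in
  real data. Palmar, pinch and twist carry weak rebounds inside
  [0.2, 0.5] s with distinct amplitudes, latencies and recovery time
  constants. The no-movement condition shows the same pre-onset trend at
  40 % amplitude and stays featureless afterwards. Condition information
  therefore exists only *after* the onset, which is why decoding peaks at
  positive times. Templates project onto the scalp through a Gaussian
  spatial map centered just left-anterior of Cz (maximal at Cz/C1/FCz,
  contralateral dominance). `effect_scale = 0` silences the templates —
  the null generator used for calibration.
* **Background noise**: ~80 randomly-phased sinusoids with 1/f amplitude
  scaling (10 µV RMS) plus white noise (3 µV RMS). Frequencies are drawn
  continuously (log-uniform, 0.1 Hz – 45 Hz) rather than on a harmonic
  grid so that no component is periodic with the trial length — a
  harmonic grid would alias into a condition-independent but
  trial-locked pattern.
* **Artifacts**: stereotyped biphasic blinks (90 µV at FP1/FP2, Poisson
  times at 2/min) projected through a steeply decaying frontal profile;
  rare focal high-amplitude bursts (probability 0.04/trial, ~350 µV) that
  exercise the ±200 µV rejection rule; 50-Hz line noise (1.5 µV).
* **Behavior**: truncated-normal reaction times (0.5 ± 0.15 s), a 5 %
  slow-trial component (2.6 ± 0.4 s) whose mass lies beyond the 2-s
  screening threshold; grasp start 1.08 ± 0.10 s after onset (inside the
  observed 0.98–1.18 s window) and condition-*identical* grasp durations
  (1.5 ± 0.3 s), so the duration ANOVA's null calibration is meaningful.

The noise and artifact levels were fixed once, at design time, so that
the end-to-end pipeline reproduces the qualitative regime of real
recordings — a total rejection fraction around 10 %, binary
grasp-vs-rest accuracies in the 60–80 % range and five-class accuracies
a modest margin above chance. They are parameters of the study
conditions the generator defines, not tuning knobs.

What the generator does *not* emulate: cue-evoked auditory potentials,
electrode drift and impedance changes, muscle (EMG) contamination,
non-stationarity across sessions, and between-subject morphology
differences beyond the RNG seed. Passing tests on synthetic data
therefore demonstrate the correctness and calibration of the *analysis*,
not expected accuracy values on real subjects.

## Preprocessing chain

`preprocess_subject()` applies, in a fixed and logged order: reaction-time
screening (RT > 2 s, strict), channel selection (the seven fronto-ocular
channels FP1, FP2, AF3, AF4, AF5, F5, F6 are dropped, leaving 33; "AF7"
is accepted as an alias of "AF5"), a 40-Hz low-pass, trial rejection on
raw-rate epochs (amplitude beyond ±200 µV; joint-probability and kurtosis
outliers beyond 3 SD), ICA ocular cleanup, common average reference, the
0.3–3 Hz zero-phase fourth-order Butterworth band-pass, decimation to
100 Hz, and epoching [−1.5, 2.5) s around the *virtual onset* (Go + the
subject's mean screened RT). Rejection statistics are computed before the
narrow band-pass, as the early low-pass is the only filtering the
rejection stage sees.

Numerical choices worth knowing:

* *Zero phase* is realized as forward–backward application of the
  order-4 Butterworth (magnitude order 8, no group delay), with
  odd-symmetric padding of 3× the filter order. Edge transients of the
  0.3-Hz corner decay over seconds; epochs are interior to the recording,
  so only the outermost seconds of the continuous data are affected.
* *Downsampling* is plain decimation; the mandatory 40-Hz low-pass and
  3-Hz band-pass precede it and act as anti-alias filters. The decimation
  factor must be an integer, which is why desk-scale simulations run at
  200 Hz rather than an arbitrary reduced rate.
* *Epoch windows are half-open* `[onset + round(w_lo·fs), onset +
  round(w_hi·fs))`, making sample counts exact (400 at 100 Hz) and the
  t = 0 sample unambiguous.
* The amplifier-side 0.05–100 Hz band-pass and 50-Hz notch are
  implemented but off by default: they describe acquisition hardware, not
  analysis.

### Statistical trial rejection

The joint-probability statistic of a trial and channel is the mean
negative log of the empirical density (50-bin histogram pooled over all
trials of that channel) of its samples; the second statistic is the
sample kurtosis. Both are z-scored across trials. Two aggregations are
offered: the default (`aggregate = "global"`) averages each statistic
across channels before z-scoring — one score pair per trial — and keeps
the false-rejection rate of clean Gaussian data near the nominal 3-SD
level (≈ 0.5 %). The any-channel alternative (`"channel"`) is far more
sensitive to focal channel noise but, with 33 channels × 2 statistics,
rejects ~15 % of perfectly clean trials by multiplicity alone; it is
available for users who want the conservative behavior, but it cannot
simultaneously satisfy a 3-SD nominal level, which is why it is not the
default.

### ICA ocular cleanup

Components are estimated by a symmetric fixed-point ICA with the cube
(kurtosis) contrast on a 1-Hz high-passed, subsampled copy of the data
and applied to the analysis data. The fixed-point step is annealed: when
the update oscillates — which it does for directions carrying little
non-Gaussian structure, since those have no stable fixed point — the
step size is damped, so spiky artifact components (blinks, bursts)
converge first and the near-Gaussian remainder freezes smoothly. The
initialisation is the identity on whitened data, making the
decomposition deterministic. A component is flagged as ocular when its
time course correlates with the EOG reference (the pre-exclusion FP1/FP2
average) above 0.7, or when ≥ 60 % of its absolute scalp weights fall on
frontal channels (montage height y ≥ 0.5). Flagged components are zeroed
and the rest is projected back; with nothing flagged the reconstruction
is the identity to numerical precision. The automated dual criterion
replaces manual component inspection, which is not reproducible; it
typically flags one to a few components, far fewer than a human
inspecting 33 components would remove, and that fidelity gap is
deliberate.

## Behavioral analysis

Reaction time is the Go-to-first-button-release interval; trials with
RT > 2 s (strictly) are discarded before anything else uses RT. The
virtual onset adds the subject's pooled mean screened RT to every trial's
Go sample — including no-movement trials, which share the Go cue.
Pooling across conditions (rather than per-condition means) keeps one
onset definition per subject; a per-condition variant would be a
one-line change but is intentionally not a flag to keep onsets
comparable across conditions. Grasp start/release are the first/last
crossings of 10 % of the per-trial force maximum after the onset —
scale-free, so transducer gain does not matter. Condition durations feed
a one-way repeated-measures ANOVA (`duration_anova()`):
F = MS_condition / MS_(condition × subject) with df = (k−1, (k−1)(n−1)),
Mauchly's W with its chi-square approximation, and a Greenhouse–Geisser
corrected p reported when sphericity is rejected (p < 0.05) — mirroring
standard reporting practice.

## MRCP statistics

Grand averages pool kept trials across subjects (the "mean over all
trials of all subjects" convention); a subject-mean mode is available via
`by = "subject"`. Confidence bands use the t distribution,
mean ± t(0.975, n−1)·SE — correct small-sample coverage regardless of
which unit (trial or subject) is averaged. Sample-wise condition
contrasts use the two-sided Wilcoxon rank-sum test per time sample: exact
enumeration of the Mann–Whitney distribution for group totals ≤ 20
without ties, otherwise the tie-corrected, continuity-corrected normal
approximation (whose error against enumeration is below 0.01 everywhere
it is used). No multiplicity correction is applied by default, matching
the field's figure convention; an FDR option exists. All-tied samples
get p = 1.

## Sliding-window shrinkage-LDA decoding

Windows of 500 ms slide in 50-ms steps over the time region of interest
(−1, 2.5] s relative to onset. Each window is labeled by its **end**
time, and end labels run over the half-open interval (−1, 2.5] — exactly
70 models, each seeing only the 500 ms preceding its label (causal), and
every window fits inside the [−1.5, 2.5) epoch. Within a window, 10
amplitudes per channel are taken on the 50-ms grid covering
[end − 0.5, end) — with 33 channels, 330 features per model. An
end-*inclusive* grid would require a sample at +2.5 s that the half-open
epoch by definition does not contain; the half-open grid is the unique
convention that keeps all three structural counts (10, 70, 330) and the
epoch definition consistent.

The classifier is a binary LDA on a shrunk pooled covariance: with
class-mean-centered covariance S (1/(n−1) normalization), target ν =
trace(S)/d, and the analytic (Ledoit–Wolf/Schäfer–Strimmer) intensity λ*
clamped to [0, 1], the weights are w = ((1−λ*)S + λ*νI)⁻¹(µ₂−µ₁) with
bias −wᵀ(µ₁+µ₂)/2. When n ≤ d the solve goes through the Woodbury
identity on the n × n Gram matrix — algebraically identical (verified in
the tests), and what makes 330-dimensional windows cheap at EEG trial
counts. λ* = 1 degenerates to the scaled mean-difference classifier;
λ* = 0 to classical LDA.

Multiclass decoding is one-vs-one (10 models for 5 classes) with
majority vote; ties break by the largest sum of signed decision values
over the tied classes' models, then by the lowest class index — fully
deterministic. Cross-validation is stratified 5-fold, repeated (10 times
by default), with repetition r reshuffling folds under seed + r; curves
are reproducible bit-exactly given the seed. The grand-average curve is
the pointwise mean of subject curves, whose peak can never exceed the
mean of subject-specific peaks (max-of-mean ≤ mean-of-max), so the
grand peak is always the more conservative summary.

Whether to use raw window amplitudes or window-mean-centered ones is
genuinely open; raw amplitudes are used, reading "potential amplitudes"
literally, and because the 0.3-Hz high-pass corner already removes the
within-epoch offset that centering would address.

### Chance bounds

The significance threshold for accuracies is the adjusted-Wald upper
bound: with p₀ = 1/k, x = n·p₀ and z the one-sided normal quantile at
1−α, p̃ = (x + z²/2)/(n + z²) and bound = p̃ + z·√(p̃(1−p̃)/(n + z²)).
One-sided, because "better than chance" is a one-sided claim; the bound
is validated against the exact binomial quantile. Quoted chance levels
for paradigms like this one depend on the per-subject trial counts left
after rejection, so the package always reports the bound for the n
actually used rather than a fixed figure.

## Problem sizes used by the tests and the acceptance script

Calibration and recovery runs simulate at 200 Hz (so decimation to the
100-Hz analysis rate keeps an integer factor), with 5-fold CV and 1–2
repetitions: the null generator (effect scale 0) over 20 seeds of
2-session subjects for chance calibration, and three 4-session subjects
for signal recovery and the pairwise-contrast power checks — binary
contrasts need the ~75 trials of the 4-session design before their
chance bounds tighten enough for stable margins. These sizes are the package's
desk-scale study conditions; the full 8-session, 1,000-Hz design is what
`grasp_config()` defaults to for real use.

## Known limitations

* The generator's condition templates differ only post-onset; real
  pre-movement planning activity may carry weak condition information
  that this model deliberately omits.
* The automated ocular criterion flags far fewer components than manual
  inspection of real data would; on real recordings the thresholds
  (0.7 correlation, 0.6 frontal fraction) likely need adjustment.
* The any-channel rejection aggregation and the 3-SD threshold cannot
  both hold at nominal level with many channels; the default trades
  focal-noise sensitivity for a calibrated false-rejection rate.
* Statistical power at desk scale is limited: pairwise grasp contrasts
  need ≥ 4 sessions of synthetic data before every distinct pair clears
  its chance bound; with 2 sessions only the aggregate properties are
  asserted.
* BrainVision support covers the multiplexed float32/int16 binary
  dialect only (vectorized and segmented variants are rejected with an
  explicit error).
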