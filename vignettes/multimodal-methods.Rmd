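---
title: "Methods: multimodal interview biomarkers and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal interview biomarkers and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindmodal)
```

# Overview

`mindmodal` analyzes structured mental-health interview sessions in which a
participant responds to seven tasks (a read sentence, a warm-up question,
and open-ended prompts about hope, secrets, anger, fear and emotional
pain), while three signal streams are recorded: audio, facial landmark
tracks, and transcripts. Screening instruments administered in the same
session define binary case labels: depression (PHQ-9 ≥ 10), anxiety
(GAD-7 ≥ 10) and suicide risk (C-SSRS ≥ Moderate). The package featurizes
each stream per task, screens features statistically, and evaluates
classifiers under leave-one-subject-out (LOSO) cross-validation with
fold-nested preprocessing, selection and fusion.

This vignette records the modelling assumptions, the tunable parameters
and their defaults, the numerical choices made where the procedure was
genuinely open, what the synthetic-data generator does and does not
emulate, and known limitations.

# Speech acoustics

The frame analysis (`analyze_frames()`) slides a window of three longest
pitch periods (`3 / f0_min` = 40 ms by default) in 10 ms steps. Per frame
it computes RMS intensity in dB and a normalized autocorrelation
`r(tau) = sum x_t x_{t+tau} / sqrt(sum_{head} x^2 · sum_{tail} x^2)`
over lags corresponding to the F0 search range (default 75–500 Hz). A
frame is voiced when the peak `r` exceeds `voicing_threshold` (0.45) and
its RMS is above a relative floor (10^-4 of the task maximum — relative,
so the analysis is invariant to amplitude scaling; digital silence is
never voiced). Among near-maximal lags (within 0.015 of the peak) the
*shortest* is taken before parabolic refinement, so an exactly periodic
signal resolves to its fundamental rather than an octave below.

Timing features segment the task by intensity: a frame is silent if more
than `silence_db` (25 dB) below the task median intensity; pauses are
silent runs of at least `min_pause_s` (0.2 s) inside the response span.
The percent pause time denominator is the full response span, so PPT and
the articulated fraction sum to 100%.

Jitter and shimmer use the *local* definitions,
`100 · mean(|T_i − T_{i−1}|) / mean(T_i)` on consecutive glottal periods
and the same on per-period amplitudes. Periods and amplitudes come from a
pulse-level analysis inside voiced regions: integer pulse peaks are found
by walking at the local pitch period, then each period is measured by
waveform matching — the cross-correlation lag (with parabolic sub-sample
refinement) between one-period windows of consecutive cycles — and each
amplitude as the RMS of a fixed-width one-period window. Raw peak picking
was rejected: peak position and height estimates vary with where the
sample grid falls inside the cycle, which floors jitter/shimmer near
0.5%; waveform matching is nearly offset-invariant (measured floors are
below 0.05%). Differences are never taken across voiced-region
boundaries, and spurious edge pulses (amplitude < 30% of the region
median, or implausible spacing) are discarded.

HNR is `10·log10(r/(1−r))` with `r` the refined autocorrelation peak,
clipped to 1 − 10^-6, averaged over voiced frames. The
"signal-to-noise ratio" is implemented as an independent quantity — the
dB ratio of mean frame power in speech vs. pause segments — rather than a
duplicate of HNR; with no detected pause it is missing.

# Facial kinematics

All coordinates are image-frame pixels with y increasing downward
("down" = increasing y). Every frame is normalized by that frame's
inter-canthal distance (right to left inner canthus), which removes
translation-independent scale (zoom/distance); frames with a degenerate
canthal distance are masked. The 14-keypoint schema is addressed by role
names (`landmark_roles()`), so alternative landmark sources can be mapped
by renaming.

Mouth geometry uses the shoelace formula on the quadrilateral (left
corner, upper lip center, right corner, lower lip center); half-areas
split that polygon along the upper–lower lip-center segment, and the
symmetry ratio is left/right half-area (left in the numerator), averaged
over frames. Frames where the two half-areas do not sum to the
quadrilateral area (a self-intersecting landmark glitch) are masked.

Articulator kinematics differentiate position by central differences over
the *actual timestamps* (robust to dropped frames), repeated for
acceleration and jerk; series are segmented at gaps longer than
`max_gap_frames` (5) and derivatives are never taken across a gap.
Directional summaries split the vertical channel: "down" maxima over
frames with positive vertical derivative, "up" maxima over the magnitudes
of negative ones, and "abs-max" the maximum absolute vertical component,
which by construction dominates both directions. Mean speed / mean
acceleration / mean jerk are means of the vector magnitudes. No smoothing
is applied by default; a moving-average window is available in
`facial_config()` because third derivatives of raw 30 fps landmarks
amplify tracking noise — analyses of real data should consider a 3–5
frame window, at the cost of attenuating genuine fast movement.

Blinks are dips of the mean two-eye eyelid distance below
`blink_fraction` (0.5) of its rolling median (2 s window), lasting at
least 2 frames and at most 0.5 s; the rate divides the count by the track
span, and requires at least 1 s of valid eye data. Eyebrow displacement
is the vertical distance from each eyebrow center to its ipsilateral
inner canthus, averaged over eyes.

# Text features

Transcripts are lowercased, every non-letter character becomes a space,
and tokens are whitespace-split (the order of lowercasing and stripping
is immaterial under these rules). No stop-word removal, stemming or
document-frequency floor is applied — function words can be informative
in interview language. The session document concatenates all task
transcripts in canonical task order. TF-IDF uses raw term counts and the
smoothed inverse document frequency `ln((1 + N)/(1 + df)) + 1`, fixed
here as the reference dialect for reproducibility, followed by L2 row
normalization (each session vector has unit Euclidean norm, controlling
for response length). In cross-validation the vocabulary and idf are
refit on training sessions only; out-of-vocabulary tokens in held-out
sessions contribute nothing. Case/control term lists take the k largest
positive and most negative linear-SVM weights, ordered by |weight| with
lexicographic tie-breaks; the weight vector is oriented empirically so
positive means case-leaning.

# Feature analysis

The full-sample screen uses two-group Kruskal–Wallis tests (kept as
stated rather than substituting the equivalent Mann–Whitney form; with
two groups they agree up to tie handling) at α = 0.05 per feature, with
**no multiple-testing correction** — the count of significant features
`k_mc`, not their identities, is the quantity carried forward, and the
per-feature α is part of that design. To weight participants equally the
screen uses one session per participant; the rule here is the earliest
session id per participant, which is deterministic and order-invariant
(the choice among a participant's sessions is not otherwise specified).

Effect sizes are Cohen's d (case minus control over the pooled SD) with a
normal-approximation 95% CI using
`Var(d) ≈ (n1+n2)/(n1·n2) + d²/(2(n1+n2−2))`. d is computed on the same
sex-standardized features used in modelling, so the forest plot matches
what the classifier sees; a zero pooled SD yields 0 for equal means and a
signed infinity sentinel otherwise. Pearson screening against assessment
totals flags |r| ≥ 0.2 with p < 0.05 — deliberately permissive for an
exploratory analysis — and covers speech and facial features only.

# Classification experiments

LOSO folds hold out all sessions of one participant. The >3% missingness
filter is applied cohort-wide once before cross-validation (the filter
expresses a data-quality property of the cohort, and applying it
per-fold would make feature sets incomparable across folds); imputation
(training-fold feature means), per-sex z-scoring (training-fold per-sex
statistics; pooled fallback for unreported or absent sex groups; SD
clamped at 10^-8) and TF-IDF remain strictly fold-nested. Per fold, the
top `k_mc` features by ascending training-fold KW p-value are selected
(lexicographic tie-break). Experiments run only if `k_mc ≥ 5`.

Models: L2-regularized logistic regression at unit penalty strength
(ridge, λ = 1/n — the standard default of regularized LR
implementations) for speech, facial and feature fusion; linear SVM
(cost 1) for text, with margins mapped to probabilities by a sigmoid
calibration fit on training margins. AUC is rank-based, so the
calibration affects only the Brier score. Evaluation uses the
Mann–Whitney AUC (ties counted ½) with DeLong 95% CIs (the CI method is
not otherwise pinned; DeLong is the standard nonparametric choice), and
the Brier score. Decision fusion combines per-modality out-of-fold scores
element-wise under all three rules (min, max, mean) and flags the best;
feature fusion concatenates the independently preprocessed and selected
matrices before a logistic model. The feature-count sweep reruns the same
machinery with the selection size forced to each k, reporting the AUC
curve and its argmax.

Inside folds, feature ranking uses a vectorized tie-corrected
implementation of the identical two-group KW statistic (the per-call
overhead of the general-purpose test dominates at corpus-vocabulary
widths); the test suite verifies exact agreement with the reference test
across randomized tied instances.

# The synthetic cohort generator

No interview corpus of this kind can be shipped, so the generator defines
the study conditions the package is tested under: 68 participants of whom
5 return for a second session (73 sessions), case-session prevalences
15/73, 21/73 and 26/73, ~77% female, ~9.3-minute interviews across the
seven tasks, and ~925 transcript words per session. Assessment totals are
drawn from the case or control side of each threshold so that labels
match the true planted states exactly; case-session counts hit
`round(prevalence × n_sessions)` exactly by construction. Condition
states co-occur independently by default.

Two layers exist. The *feature-level* simulator emits standard-normal
feature matrices with plantable case shifts; planted effects are realized
exactly in-sample (group-mean-centered noise) by default, so recovery
checks measure the pipeline's estimation fidelity rather than generator
sampling noise (population-level noisy effects are available via
`exact_effects = FALSE`). The *raw-signal* generator writes WAV audio,
landmark CSVs and transcripts. Audio is a source–filter surrogate: a
damped-sinusoid glottal pulse train (500 Hz formant, pulses truncated
below one period) with sinusoidal F0 modulation, speech/pause
interleaving, and jitter/shimmer planted as a deterministic
(+1, +1, −1, −1) period-4 perturbation cycle. That cycle is chosen so the
realized local jitter/shimmer equal the requested percentages exactly,
consecutive periods misalign less than periods two apart (pitch tracking
stays on the fundamental), and the 4T subharmonic falls outside the F0
search range for vowel-range F0 (the planted-jitter design assumes
F0 < 300 Hz). Landmarks combine a fixed face geometry, slow translation
drift and zoom (exercising normalization), band-limited lower-lip/jaw
motion scaled by an articulation amplitude, scheduled blinks
(`round(rate × duration)` dips at jittered regular times, so recovery is
not Poisson-noisy), and a slow eyebrow cycle. Group effects are planted
at generator-parameter level: higher pause fraction for depression and
suicide-risk cases, reduced articulation amplitude for anxiety cases, and
condition-tilted transcript vocabularies.

What the generator does **not** emulate: real spectral structure of
speech (one formant, no aspiration noise model beyond a flat floor), head
pose and non-rigid face deformation, landmark tracker failure modes,
disfluencies and syntax in transcripts, and any correlation structure
between modalities beyond the shared condition state. Passing tests on
synthetic cohorts therefore certify the *pipeline's* correctness and
calibration, not clinical validity on real data.

# Numerical choices and degenerate inputs

* Empty or all-silent audio returns a structured "no speech" result;
  features become missing values that flow into the imputation policy.
* Fewer than 10 voiced frames: all frequency features missing.
* Autocorrelation `r` is clipped to 1 − 10^-6 before the HNR log-ratio.
* Zero-SD features in z-scoring are clamped, not dropped; constant
  features get p = 1 in the screen and an unflagged note in the Pearson
  report.
* Single-class training folds score 0.5 with a warning; the ridge solver
  requires two columns, so single-feature fits carry an inert zero
  column.
* DeLong CIs require two observations per class; with fewer the CI is
  undefined (NA) while the point AUC is still reported.

# Test and calibration problem sizes

The test suite exercises the speech loop on 2–10 s synthetic vowels (20
random F0/jitter/shimmer settings, 5% relative recovery), facial tracks
of 6–30 s, and feature-level cohorts of 24–80 participants; the
acceptance checks use the 73-session study-condition cohort for
accounting and type-I calibration (1,000 null features), a 70-participant
cohort with ten planted d = 1.0 features for recovery and fusion, and
20 replicates of a 100-participant balanced null cohort for LOSO
calibration. These sizes are the package's chosen design points for fast,
reproducible verification.

The null-calibration design deserves a note. The chance-level LOSO AUC is
*not* tightly concentrated at 0.5: holding out a case leaves a
control-heavier training fold, whose unpenalized intercept anti-ranks the
held-out session (a known pessimistic bias of leave-one-out at small n),
and the spurious alignment between the fitted coefficient direction and
the class-mean difference makes the chance-level AUC fluctuate with
relative χ²_k noise — roughly independent of cohort size and shrinking
only with the number of modelled features, with winner's-curse selection
(k far below the feature count) inflating it further. The calibration
check therefore models all 77 features in every fold of a 100-participant
balanced cohort, where the chance-level SD is about 0.07 and the
0.35–0.65 acceptance band is a better-than-2σ criterion. With, say, 5
features selected from 30 at n = 80 the same pipeline honestly strays
outside that band in roughly a quarter of replicates — an instance of the
small-sample overfitting that motivates fold-nested selection in the
first place.

# Limitations

* The acoustic surrogate cannot validate measures it does not model
  (e.g., HNR under realistic aspiration noise, formant-dependent
  effects).
* Jerk from raw 30 fps landmarks is noise-amplifying; real-data use
  should consider the smoothing option and treat jerk features with
  caution.
* The per-feature α = 0.05 screen with no multiplicity correction is a
  design inherited from the analysis it implements; `k_mc` counts will
  include false positives by construction.
* LOSO AUC at double-digit cohort sizes carries the variance discussed
  above; confidence intervals should always be reported alongside point
  AUCs.
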