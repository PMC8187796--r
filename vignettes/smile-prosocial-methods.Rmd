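---
title: "Methods: smile detection and prosocial-behavior prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smile detection and prosocial-behavior prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosmile)
```

## The problem

In robot-assisted therapy sessions, children interact with a small
humanoid robot that walks with them and occasionally falls. Two prosocial
behaviors (PB) are of interest: helping the robot walk and helping it
stand up. The working hypothesis is that a child's smile — detected from
video annotation or, where the face is off-camera, from facial surface
EMG — precedes prosocial behavior, so that smiling can be used to predict
and ultimately facilitate it.

`prosmile` implements that analysis as a reusable pipeline over four
binary case flags coded from the 10 s before each (possible)
prosocial-behavior onset: smiling `S`, heading toward the robot `H`,
approaching the robot `A`, and prompting by a therapist or parent `P`,
plus the outcome `PB`. Because the original recordings are not required,
the package ships seeded generators that emulate both the EMG signal
structure and the behavioral event chain; every downstream stage is
exercised against their ground truth.

## The EMG smile-detection chain

The detection chain mirrors standard facial-EMG practice:

1. **Band-pass 50–350 Hz.** Surface-EMG energy of the smile muscles lies
   well above typical motion artifacts (< 20 Hz) and below half the
   sampling rate. The filter is a 4th-order Butterworth applied
   forward-backward (`signal::filtfilt`), i.e. zero-phase, so burst onsets
   are not shifted — an 8th-order magnitude response in effect. The tests
   verify ≥ 40 dB attenuation at 5 Hz, unity gain within 5% at 200 Hz, and
   symmetry of a filtered symmetric pulse to 1e-9 of its peak.
2. **ICA unmixing.** Each electrode sees a superposition of several
   muscles. A deflation-based fixed-point ICA (tanh contrast, seeded
   random initialization, tolerance 1e-8, at most 500 iterations per
   component) is run on centred, whitened data. Components are ordered by
   explained channel variance and sign-fixed to non-negative skewness.
   The full 4×4 unmixing matrix (whitening included) is stored on the
   trained classifier and reused verbatim at inference time, so training
   and classification share one projection. A rank-deficient channel
   covariance (e.g. a constant channel) is an error that names the
   degenerate channels. No ICA implementation for R is bundled with the
   package's dependencies, so the algorithm is implemented here and
   validated against known mixtures: on noiseless super-Gaussian sources
   the tests require best-assignment |correlation| ≥ 0.95.
3. **RMS envelope.** Non-overlapping 100-ms frames (10 Hz feature rate,
   matching the per-second annotation resolution with margin). A trailing
   partial frame is discarded. The envelope is scale-equivariant and the
   RMS of a unit sine with integer periods per frame is 1/√2 to 1e-6.
4. **Per-participant ANN.** One hidden layer (default width 16, logistic
   output, weight decay 1e-3) on standardized RMS features, fitted with
   `nnet`. Coder smile labels are the teaching signal; frames inside the
   neutral-baseline interval are forced negative; frames whose broadband
   power exceeds the 99th percentile are excluded as noisy — the
   operationalization of preferring low-artifact training data. Early
   stopping is realized as selecting, from a common seeded weight
   initialization, the iteration budget (60/150/300) with the lowest
   log-loss on a seeded 20% validation split, then refitting at that
   budget. Everything derives from one integer seed, so training is
   reproducible bit for bit.
5. **Binarization and smoothing.** Probabilities are cut at 0.5
   (configurable), detections separated by < 200 ms are merged and
   intervals < 300 ms dropped, suppressing frame flicker. Both thresholds
   are arguments of `frames_to_intervals()`.
6. **Gap filling.** `estimate_unobserved()` clips the detected track to
   the camera-unobservable intervals only; the video annotation keeps
   authority everywhere else. `fuse_smiles()` then unions the two tracks.
   Because EMG intervals live inside the unobservable set and video
   intervals outside it, fusion is exactly conservative: fused duration
   equals video duration plus EMG duration.

## Annotation conventions

All intervals are half-open `[onset_ms, offset_ms)` on a 0-based
millisecond session clock; instantaneous events are zero-length rows. The
TSV dialect is `onset_ms<TAB>offset_ms<TAB>label<TAB>coder`, one file per
session per coder, with a controlled label vocabulary.

Choices the annotation procedure leaves open were fixed as follows:

- **Per-second coding.** A second of the 10-s pre-onset window is coded
  positive for a channel when that channel's intervals overlap the 1-s
  bin by ≥ 500 ms (majority coverage). A stricter or looser rule is a
  single argument (`overlap_ms`).
- **Heading flag.** `H` is true when ≥ 8 of the 10 coded seconds are
  head-positive — "maintained" head direction, configurable via
  `head_seconds`.
- **Smile flag.** `S` is true when any fused smile overlaps the window at
  all; smiles are sparse enough that a coverage quota would mostly
  measure smile length, not presence.
- **Cases without prosocial behavior** have no onset to anchor the
  window, so the reference time is 11 s after the situation's robot
  anchor (movement or fall start), which coincides with the onset the
  generator uses when behavior does occur.
- **Window (d) anchor.** The minute before the falling-situation
  prosocial behavior is the default; anchoring on the robot's fall
  instead is available via `d_anchor = "robot_fall"`, and the anchor used
  is reported in the output.
- **ICC.** Two-way random-effects, absolute-agreement, single-measure
  ICC(2,1), with F = MSR/MSE on (n−1, n−1) degrees of freedom for two
  coders and the usual Satterthwaite-based 95% interval. The consistency
  form is available for comparison; identical columns short-circuit to
  ICC 1 with a degenerate interval.

## The probability model

`build_joint_table()` keeps exact integer counts and exposes two
arithmetic modes. The *rounded* mode (default for reports) computes on
proportions rounded half-up to two decimals — the convention of printed
small-sample tables, under which the 36-case reference counts
(15, 3, 8, 10) give P(PB|S) = 0.42/0.5 = 0.84, P(PB|S̄) = 0.22/0.5 = 0.44
and a 66% smile share of prosocial behavior. The *exact* mode computes on
counts (15/18 = 0.833, 8/18 = 0.444, 65%) and satisfies the Bayes
identity and the law of total probability to 1e-12. Reporting both modes
side by side documents the rounding dependence instead of hiding it.
Half-up rounding is implemented explicitly because base R rounds
half-even.

Prediction uses conditional probability tables: `P(PB | pattern)` by
relative frequency for every observed pattern of the chosen predictor
subset of {S, H, P}, with unseen patterns falling back to the training PB
rate. `A` is deliberately not a predictor: in the observed data prosocial
behavior always follows once smiling, heading and approaching have all
occurred, so approach carries no additional predictive information; the
flag is retained on case records for the event-chain checks. The decision
rule is threshold 0.5 with ties resolved to the training-majority class;
no pseudocounts by default (add-one smoothing is an option). Subject-wise
leave-one-out cross-validation holds out one participant's cases at a
time and averages accuracy unweighted over held-out participants (the
quoted procedure averages per participant; per-case weighting is an
option). The implementation is property-tested against a brute-force fold
oracle on seeded toy sets of up to 8 cases.

## What the generators emulate — and what they do not

**Sessions.** The behavioral generator is a Bernoulli chain per
situation: the robot moves; the child smiles with probability
`p_smile_given_robot_movement`; heading follows with
`p_head_given_smile` (or `p_head_given_no_smile`); approach with
`p_approach_given_head`; approach yields prosocial behavior with
`p_pb_given_approach`; when no smile appears, prompting occurs with
`p_prompt_given_no_smile` and succeeds with `p_pb_given_prompt`. The
chain has a closed-form (S, PB) joint (`session_joint()`), and the
defaults are calibrated so that joint is exactly (0.42, 0.08, 0.22, 0.28):
P(S) = 0.5; P(PB|S) = 0.875 × 0.96 × 1 = 0.84, with approach
deterministic given the chain completed (matching the observation that
prosocial behavior always followed smile + heading + approach); and
P(PB|S̄) = 0.44 via a 0.25 heading rate without smiles, 0.5 prompting and
a solved prompt-success probability of 10/19. The generator writes the
outcomes onto session timelines (anchors at fixed layout times, smile
onsets jittered within the window) such that re-coding the timeline with
the annotation module recovers the drawn flags exactly — a conservation
property the tests enforce for every generated session. The study-sized
default (6 + 6 participants, 2 ASD sessions, 1 TD session, 2 situations)
yields 36 cases.

**EMG.** Channels are a fixed, well-conditioned linear mixture of two
smile-muscle sources (band-limited 50–350 Hz noise bursts with 100-ms
raised-cosine ramps, active only inside ground-truth smile intervals) and
one always-on tonic background, plus white sensor noise and 5×-amplitude
sub-20-Hz motion-artifact bursts. `snr_db` (default 20) sets the smile
burst amplitude relative to the unit-variance background; 1000 Hz
sampling (the band's Nyquist constraint demands > 700 Hz), 4 smiles and 3
artifacts per minute, smile lengths 1–4 s. Smile intervals can also be
imposed, which is how the pipeline ties a session's EMG stream to its
annotated timeline.

Deliberately **not** modeled: motor-unit physiology, electrode-skin
impedance drift, cross-talk asymmetries, EMG of non-smile facial
expressions, and any within-smile amplitude dynamics beyond the ramped
envelope. Detection scores on this synthetic data (the suite requires
frame F1 ≥ 0.90 on a clean held-out session at the default SNR, and total
estimated smile duration within 15% of truth at 10 dB) therefore certify
the correctness and stability of the chain, not clinical-grade
performance on real recordings — real sessions contain artifact classes
the band-pass cannot remove and expression overlap no four-source mixture
produces.

## Numerical choices and degenerate inputs

- Intervals are merged when overlapping *or* adjacent; totals are
  computed on merged copies, so double counting is impossible.
- Largest-remainder apportionment turns target proportions into case
  counts that sum exactly to n (ties broken by cell order).
- Probability tables reject empty case lists; conditioning on an event
  of zero mass is an error rather than NaN.
- The ICA whitening step errors on near-zero-variance channels (named)
  and on collinear channels, rather than amplifying numerical noise.
- Classifier training errors on single-class labels and on fewer frames
  than hidden units.
- All generators save and restore the caller's RNG state; identical
  configs give bit-identical output.

## Problem sizes

The test suite runs synthetic EMG at 60–120 s per recording, ICA on up to
20,000 × 4 samples, calibration checks on 10,000 chain draws, LOO-CV
oracle comparisons on toy sets of ≤ 8 cases, and two full pipeline runs
with four sessions of 260 s each — sizes chosen so the whole suite
completes in about a minute on one core while keeping every statistical
check comfortably powered. The acceptance script touches only the 36-case
table, the session generator and the participant roster, and runs in
seconds.

## Known limitations

- The ANN architecture, training split and noise-exclusion criterion of
  the original signal-processing chain are unspecified upstream; the
  defaults here (width 16, 20% validation, 99th-percentile power cut) are
  declared choices, and all are arguments.
- ICC supports exactly two coders, which is the design of the annotation
  protocol; more coders would need a different reliability model.
- The per-participant classifier assumes the unmixing learned at training
  time remains valid across the session (fixed electrode placement).
- LOO-CV accuracies on 36-case samples have large folds-level variance;
  the package reports them but deliberately attaches no significance
  claims.
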