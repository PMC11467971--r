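---
title: "Spatial-filter decoding of exoskeleton-assisted motor imagery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-filter decoding of exoskeleton-assisted motor imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A brain–computer interface built around an upper-limb exoskeleton must
distinguish two states from 16-channel sensorimotor EEG: the wearer passively
receiving flexion/extension movement (baseline), and the wearer performing
kinesthetic motor imagery while receiving the same passive movement
(MI+passive), with the exoskeleton cycling at either 30 rpm (low) or 85 rpm
(high). The physiological handle is event-related desynchronization (ERD):
during motor imagery the mu (8–12 Hz) and beta (14–30 Hz) sensorimotor
rhythms lose band power over contralateral motor cortex.

`cspmi` implements the complete comparison of three spatial-filtering
pipelines for that binary decision — classic broadband CSP, filter-bank CSP
with mutual-information feature selection (FBCSP), and a two-layer
spatial–spectral variant (FBCSSP) — under two temporal segmentation regimes
and a significance analysis of the between-method differences. Because no
public recording of the protocol exists, the package ships a
protocol-faithful synthetic generator with known ground truth, so every
stage is testable end to end and the study runs as a fully reproducible
simulation.

## The synthetic cohort

`generate_session()` renders one session of the acquisition protocol: a
120-s passive baseline, then 30 trials of beep (1.25 s), no-action (drawn
uniformly from 2–3 s) and MI+passive movement (10 s), 15 trials per speed in
seeded random order; 125 Hz sampling on the 16-electrode sensorimotor
montage. Two sessions per subject, ten subjects by default.

The signal model is deliberately the minimal one exhibiting the structure
the methods assume:

* latent sources are band-limited Gaussian oscillations (zero-phase
  filtered white noise, unit variance) plus a 1/f background
  (`onef_sd = 0.5`);
* channels are `mixing %*% sources` plus white sensor noise
  (`noise_sd = 0.5`); the default mixing has orthonormal columns scaled to
  a nominal gain of 2, fixed once and perturbed per subject by a small
  seeded Cayley rotation (`rotation_sd = 0.05` rad) to emulate
  inter-subject variability;
* the ERD is a multiplicative amplitude factor `sqrt(erd_attenuation)` on
  the discriminative mu source during MI phases only; the baseline is the
  unattenuated reference. Defaults are 0.5 (low speed) and 0.4 (high
  speed) — a moderate-to-strong ERD. The speed difference is deliberately
  small, and its magnitude is an arbitrary choice: nothing in the protocol
  pins it down, and it should be treated as a knob, not a fact;
* nuisance sources carry slow log-normal gain jitter (sd 0.2 of the log
  gain, piecewise-constant over 5-s blocks) emulating trial-to-trial power
  nonstationarity. The discriminative source's gain is held fixed so the
  planted effect size is exactly the configured attenuation — that is what
  lets `measure_ground_truth_erd()` verify the generator against its own
  configuration (realized ratios match within ~10% over 15 trials).

What the generator does **not** emulate: realistic volume-conduction
leadfields, ocular/muscular artifacts, line noise, inter-session
nonstationarity beyond the seeded rotation, or non-Gaussian rhythm
dynamics. Passing tests on this cohort therefore demonstrate the internal
correctness and statistical behaviour of the pipeline, not field
performance on real EEG.

Amplitudes are nominal microvolts, but only relative power matters: every
downstream feature is variance-based and scale-normalized.

## Preprocessing

All decoding operates on zero-phase band-passed signals. The filter is a
5th-order Butterworth band-pass applied forward and backward (squared
magnitude response, zero net phase), with even-extension padding of three
filter lengths at both ends to suppress edge transients. The broadband
analysis band is 8–30 Hz; no common-average reference or other spatial
preprocessing is applied, so the spatial filtering under study is the only
spatial operation.

Epoching: one 10-s epoch per MI marker; the continuous baseline is cut into
consecutive non-overlapping 10-s pseudo-trials (12 of them), giving the
baseline class the same trial geometry as the MI class. The 10-s choice is a
design decision — the protocol does not prescribe how the baseline enters
classification — and it accepts a mild class imbalance (12 baseline vs 15 MI
trials per speed problem), which the evaluation handles by stratified group
assignment rather than resampling.

Two temporal segmentations:

* **TW0 (dynamic)** — sliding 1-s windows at 50% overlap. With 125 samples
  per window the half-window hop is ambiguous; the package uses
  `hop = floor(w/2) = 62` samples, giving 19 windows per 10-s trial. Both
  parameters are configurable.
* **TW3 (static)** — a single 1–6 s crop per trial, interpreted relative to
  trial onset (the reference point is another choice the protocol leaves
  open; pseudo-trial onset plays the same role for the baseline class).

All sample intervals are half-open with 0-based onsets, so epoching,
windowing and cropping compose without off-by-one drift
(`TW3 ∘ TW3 = TW3` on composed intervals is a tested invariant).

## The three spatial-filter methods

**CSP.** For class covariances `Ca, Cb` (per-trial trace-normalized,
equal-weight averaged — the dominant CSP convention, which makes classes
amplitude-comparable), the filters solve `Ca w = λ (Ca + Cb) w`. The package
whitens the composite and keeps the 3 largest-λ and 3 smallest-λ
eigenvectors ("three patterns, six filters"), scaled so
`w' (Ca + Cb) w = 1` and sign-fixed so each filter's largest-magnitude
coefficient is positive. A relative ridge of `1e-9` on each covariance
diagonal guards against rank deficiency from short windows; eigenvalue ties
break by the stable sort order. Features are normalized log-variances
`log(var_p / Σ var_q)` of the projected signals — scale-invariant; the plain
`log(var_p)` form is available behind a flag.

**FBCSP.** The same CSP fitted independently in the three sub-bands 8–15,
15–22, 22–30 Hz, concatenating 18 features, of which the 6 with the highest
mutual information with the class label are kept. The MI estimator is a
deterministic plug-in: 10 equal-frequency bins per feature, MI in bits, ties
broken toward the lower feature index. Both the estimator and `k = 6` are
design choices (the selection criterion in the source literature is a
Parzen-window estimator; a histogram plug-in is deterministic and testable,
and `k = 6` makes FBCSP's feature count match CSP's).

**FBCSSP.** Layer 1 is the per-band CSP (no selection); each trial's
per-band projections are stacked into an 18-surrogate-channel trial, and
layer 2 is a CSP on those surrogates (3 pairs, 6 features). Layer 2 averages
the surrogate covariances **without** per-trial trace normalization: layer 1
already calibrates each component (`w'(Ca+Cb)w = 1`), renormalizing per
surrogate trial would scramble the relative band powers layer 2 exists to
weigh, and the unnormalized form makes the construction exactly consistent —
with a single-band bank retaining all components, layer 2 reproduces the
single-layer eigenvalue spectrum to numerical precision (a tested
invariant).

## Evaluation

LDA with a pooled within-class covariance (ridge `1e-6 ×` mean diagonal, so
duplicate or collinear features are harmless), empirical priors, ties going
to the baseline class. The positive class is MI+passive, so the
false-positive rate reads "baseline misread as imagery" — the costly error
for a BCI trigger. Metrics are `ACC = (TP+TN)/total` and `FPR = FP/(FP+TN)`.

Cross-validation is **cross-trial**: folds partition source trials
(groups), stratified by class with a seeded permutation, and every window
inherits its parent trial's group, so windows from one trial never appear on
both sides of a split. In `run_study()` the *entire* method — band-pass
projections, CSP fits, feature selection, LDA — is refitted on the training
groups of every fold (`cross_validate_refit()`); this is the protocol under
which out-of-fold performance honestly reflects each method's capacity to
generalize, and it is what exposes the two-layer method's overfitting in
the stress analysis below. The feature-level primitive
`cross_validate()` (LDA refit only, filters fixed) is exported for
feature-table workflows; with full-session filter fitting it measurably
inflates all methods and flattens their differences, so the study pipeline
does not use it. TW0 windows are scored individually by default — a per-trial
majority-vote mode exists behind `cross_validate(vote = TRUE)` but is off,
since the study design describes no vote — and per-fold metrics are
macro-averaged over the five folds. Per-subject values entering the statistics are fold means.

## Between-method statistics

For every condition cell (session × segmentation × metric × speed) and
method pair, the package reports Shapiro–Wilk normality p-values and a
Levene test centered at the mean (reported, not used as a gate), then a
**one-sided pooled-variance two-sample t-test** at α = 0.05. The direction
encodes the study's alternative hypothesis — CSP better than its variants:
greater mean for ACC, smaller mean for FPR; in the FBCSP-vs-FBCSSP pair the
simpler method takes the "better" slot. If both samples are exactly
constant the statistic is defined as 0 (equal means) or ±∞, rather than
failing. Two points are worth stating loudly:

* the test is the *unpaired* two-sample t-test applied to per-subject
  values that are in fact paired; this mirrors the stated analysis design
  rather than the statistically ideal choice;
* **no multiple-testing correction** is applied across the 48 comparison
  cells, again as a faithful-reproduction choice. Daggers in the
  significance matrix are per-cell α = 0.05 decisions.

The rendered matrix (rows: method pairs; columns: segmentation × metric ×
speed; marks: `†` significant, `~` not) mirrors the familiar per-session
significance-table layout.

## The stress configuration

`fbcssp_stress_truth()` is a deliberately engineered ground truth under
which the two-layer method loses: a moderately attenuated mu source
(0.6/0.55) confined to the first bank band, and five nuisance sources at
9–14 Hz — inside that same band — with strong gain jitter (log-sd 1.0).
Within the narrow band the jittered nuisances produce spurious sample
eigenvalue extremes that outrank the genuine effect, so layer 1's 6-of-16
selection tends to discard the discriminative subspace and layer 2 compounds
the loss; broadband CSP sees the same nuisances against a three-times-wider
noise floor, which damps their spurious extremes, and keeps the source. In
the packaged study this yields a consistent CSP-over-FBCSSP accuracy gap
and daggered CSP-vs-FBCSSP cells in the majority of condition cells in the
majority of seeded reruns. It is a designed demonstration of a known
failure mode, not evidence about any particular real dataset.

During the design of this configuration two facts became clear and are
worth recording: under the synthetic source model, band isolation usually
*helps* narrowband effects (the bank's narrower noise floor raises
within-band SNR), and cross-band redundancy protects broadband effects; a
configuration in which FBCSSP genuinely discards the signal while CSP keeps
it requires the in-band interference structure above, and honest per-fold
refitting — with filters fitted on the full session the overfit leaks into
every fold and the gap disappears.

## Problem sizes and costs

The packaged defaults run the full design — 10 subjects × 2 sessions × 3
methods × 2 segmentations × 2 speeds × 5 folds = 1200 evaluation rows —
in a few minutes on one core; the unit-test suite uses a reduced protocol
(8 channels, 6 trials, 40-s baseline, 3 folds) chosen to exercise every
code path at a fraction of that cost. Simulation seeds derive
deterministically from a single master seed, so every table in the output
is bit-reproducible.

## Known limitations

* The generator's linear instantaneous mixing and Gaussian band-limited
  sources are a favourable environment for variance-based spatial filters;
  all methods will look better here than on artifact-laden EEG.
* The baseline pseudo-trial construction assumes the baseline segment is
  stationary; real pre-task baselines drift.
* `k_selected`, bin counts, ridge sizes and the speed-effect magnitude are
  defensible defaults, not tuned optima.
* EDF input/output is not implemented; the interchange format is the
  delimited-matrix + JSON-sidecar fixture, which round-trips losslessly.
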