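---
title: "Decoding choice- and action-predictive BOLD signals: models and methods"
author: "bolddecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding choice- and action-predictive BOLD signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bolddecode)
```

## The scientific problem

During an item-recognition decision, a subject judges whether an image is
old or new and then reports the judgment with a motor act. Within any one
subject the memory choice and the motor response are perfectly collinear:
a classifier that reads out "old vs. new" from brain activity is equally
a classifier of "eye vs. hand". The experimental design this package
models breaks that collinearity *across* subjects: two counterbalanced
groups of equal size receive reversed choice-to-effector mappings (group
A1 reports "old" with an eye movement, group A2 with a hand movement).
Leave-one-subject-out (LOSO) decoding then isolates signals whose spatial
code is *shared* across subjects: a choice decoder generalizes only where
activity tracks the memory decision irrespective of the mapping, and an
action decoder only where activity tracks the effector. Within-subject
decoding, by contrast, also sees signals that depend on the subject's own
choice-response association.

The package provides the full analysis chain as reusable, tested
components: trial-schedule generation with the factorial design, a
forward simulator that plants condition-dependent activity patterns into
noisy 4D BOLD data, GLM estimation (condition-level, execution-phase
residualization, single-trial beta series), searchlight and regional
decoding, evidence-modulation statistics, frame-wise temporal decoding
and temporal generalization.

## Experimental design encoded in the schedules

The retrieval session has 360 trials in 12 runs of 30; each run holds
five trials of each of six stimulus types. Types map deterministically
onto memory status and decision evidence: `1x`/`3x`/`5x` are old items
whose evidence grows with encoding repetitions, and `SPR`/`SR`/`U` are
new items whose evidence grows with lure distinctiveness. A trial shows
the image for 1.5 s, holds an 8 s delay, then issues a 1 s go-signal; a
jittered inter-trial interval of 2-4 frames (TR = 1.914 s) follows.
The encoding session deals 600 presentations of 240 images (60
categories x 4 repetition roles) into 15 blocks of fixed composition.

Choices come from a simulated observer: per trial the choice equals the
true status with probability `p_correct[status, evidence]`. The default
table (old: 0.50/0.75/0.87, new: 0.65/0.75/0.87 for low/middle/high)
reproduces the characteristic behavioral profile — graded improvement
with evidence, chance performance for weakly encoded old items, and a
low-evidence advantage for new items. `mixed_anova()` runs the standard
split-plot ANOVA (status x evidence within, association group between)
on the resulting accuracy table.

Decisions the design left open, fixed here: group A1 is old-to-eye (the
direction is arbitrary and recorded in the cohort sidecar); the ITI is
uniform over {2, 3, 4} frames; target side is balanced within run; the
go-signal window is 1 s, matching the execution regressor duration.

## The forward model

Each planted pattern is a set of in-mask voxels with unit-norm,
zero-mean-distribution weights. Its contribution to voxel $v$ at time
$t$ is

$$ s_v(t) = w_v \, a \, g(\text{evidence}) \, \sigma(\text{group}) \,
   d(\text{trial}) \; (h * \text{box}_{[\tau, \tau+\delta]})(t), $$

with amplitude $a$, evidence gain $g$, group sign $\sigma$, driver sign
$d \in \{-1, +1\}$ (the trial's choice, response, image type or target
side), and an HRF $h$ convolved with a boxcar starting `onset_lag_s`
after image onset. Noise is AR(1) (marginal sd 1, lag-1 coefficient 0.3)
plus a random polynomial drift per run (order 2, per-frame sd 0.5) —
the simplest model that exercises detrending and autocorrelation without
claiming physiological realism.

The default suite plants five disjoint sites:

* **choice** — early (no lag), transient (2 s), shared across subjects,
  amplitude scaled by evidence (gains 0.5/1/1.5);
* **action** — driven by the response, 6 s lag, sustained through the
  go-signal (4.5 s), shared, evidence-insensitive;
* **association** — driven by the choice, 6 s lag, sign tied to the
  subject's group (A1 = +1, A2 = -1) *and* spatially idiosyncratic: its
  unit-norm weights are re-drawn deterministically per subject. The sign
  flip alone cannot produce a signal invisible to both between-subject
  decoders — a group-sign flip on shared weights is algebraically
  identical to a response-shared pattern, because the flip coincides
  with the mapping reversal. A code that is decodable within but not
  between subjects must differ spatially across subjects, which is what
  the idiosyncratic redraw implements;
* **image_type** and **target_side** — early stimulus-locked controls.

Amplitude calibration: the default amplitude 1 (relative to unit noise
sd) was chosen from a one-off sweep as the smallest value whose
regional decodabilities fall in a realistic range while remaining
clearly recoverable at desk scale (the README's worked example shows
the resulting accuracies: roughly 0.7-0.9 by evidence level on beta
series, temporal peak ~0.8). Larger amplitudes saturate accuracies
near 1, which no real experiment of this kind produces.

What the generator does *not* emulate: anatomy, spatial autocorrelation
and smoothing, motion and physiological noise, inter-subject spatial
misalignment, HRF variability. Passing tests therefore demonstrate that
the analysis chain recovers what it is designed to recover under its own
forward model — not that it would behave identically on real data.

## GLM and datasets

`make_hrf()` is the gamma-family kernel
$h(t) = ((t-\delta)/\tau)^{n-1} e^{-(t-\delta)/\tau} / (\tau (n-1)!)$
for $t \ge \delta$, unit-peak normalized; the defaults ($n = 3$,
$\tau = 1.25$ s, $\delta = 2$ s) peak at 4.5 s. Regressors are built at
frame resolution with onsets rounded to the nearest frame (the schedules
are frame-locked at this TR, so no microtime grid is needed).

The condition GLM crosses memory status x evidence x accuracy into up to
12 decision regressors (1.5 s boxcar at image onset) plus response x
accuracy into 4 execution regressors (1 s boxcar at the go-signal), with
per-run intercept and linear drift as nuisance. Empty cells drop with a
warning.

Two derived datasets feed the decoders:

* `residualize_execution()` projects the data onto the orthogonal
  complement of the execution + nuisance span. A projection (rather than
  subtracting fitted contributions from a joint model) makes the
  operation idempotent and the residuals exactly orthogonal to every
  execution column, at the cost of also removing the (small) component
  of decision-phase activity that lies in that span.
* `single_trial_betas()` gives every trial its own regressor and
  estimates all of a run's trials jointly (least-squares-all), with
  execution and nuisance columns as covariates. Least-squares-separate
  is available as an option; note it is biased when per-trial amplitudes
  vary, since its single "other trials" regressor assumes a common
  amplitude.

## Decoding pipeline

Single-trial maps are z-scored across voxels (removing the overall
activation level, so classification rests on the spatial distribution),
then each voxel is detrended and z-scored across trials. The classifier
is a soft-margin linear SVM with C = 1, solved by deterministic dual
coordinate descent (LIBLINEAR's algorithm and stopping criterion,
implemented in compiled code; the intercept is absorbed as a constant
feature). The test suite verifies the solver against a
projected-gradient QP oracle on fixed toys and against an independent
SVM library.

Searchlights scroll a radius-3 sphere (123 offsets; clipped at mask
edges) across all in-mask centers under LOSO cross-validation, after
retaining a balanced 50% of each subject's trials for tractability. No
feature selection is applied at the searchlight stage. Accuracy maps are
tested voxelwise against chance (one-sample t on subject accuracies —
the paired-vs-chance formulation reduces to this), thresholded by
Benjamini-Hochberg FDR at α = 0.01 and by cluster extent
(6-connectivity; the whole-brain extent of 50 voxels must be scaled down
with the grid). Regional analyses add ANOVA feature selection (k = 50,
training folds only; deterministic lowest-index tie-break) and run
separately per evidence level; the evidence effect on accuracy is tested
with `accuracy ~ evidence + (1 | subject)` (evidence coded -1/0/+1,
REML, Satterthwaite-type test on the slope), falling back to a
subject-wise slope t test when the random-intercept fit is singular.
Accuracies are treated as Gaussian at the subject level, which is
reasonable at 30+ test trials per cell; no logit transform is applied.

Temporal analyses extract the first 7 frames from image onset (frame 1 =
first acquisition at or after onset; outputs also report seconds) from
the residual dataset and decode each frame independently; within-subject
folds are grouped by contiguous runs (k = 7) to avoid temporal leakage,
and the within-subject analyses do not subsample trials. The temporal
generalization matrix trains at frame i and tests at frame j under the
same folds, so its diagonal reproduces frame-wise decoding exactly.
Bonferroni families follow the analysis structure: frames x ROIs for
time courses, 49 x ROIs for generalization matrices. Peak detection
compares each point with its neighbors; plateaus report their first
frame and endpoints are excluded.

One caveat the synthetic experiments make explicit: an "early transient"
pattern still leaves a small HRF tail in late frames (the response to a
2 s event has ~10% of its peak amplitude 9-11 s after onset), so
early-trained classifiers can sit a fraction of a percent above chance
at late test frames. At the calibrated amplitude this residual is within
statistical noise of chance, as the acceptance suite verifies.

## Problem sizes and determinism

The package's own validation uses desk-scale cohorts chosen to keep the
full suite fast while preserving every qualitative contrast: 12 subjects
on a 20^3 grid with the full 360-trial design for the dissociation
analyses, 6-8 subjects on 10-12^3 grids for module tests, 20 pure-noise
cohorts for null calibration, and 200 simulated accuracy tables for the
power analysis of the evidence-slope test. Every stochastic step takes
an explicit seed; `run_pipeline()` derives per-stage seeds from one
master seed and records them, with result hashes, in its manifest.

## Known limitations

* The noise model is temporally but not spatially structured; searchlight
  null distributions on real data are wider than on this generator.
* The observer model draws choices independently across trials (no
  sequential effects, no reaction times).
* Between-subject decoding of strongly idiosyncratic signals saturates
  per-subject accuracies toward 0 or 1; cohort means are then
  high-variance, which the tests handle with subject-level standard
  errors.
* `run_pipeline()` at the full default configuration (four label sets,
  whole-grid searchlights) is minutes of compute; the configurable
  `centers`, `site_voxels` and grid parameters exist to scale studies to
  the question at hand.
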