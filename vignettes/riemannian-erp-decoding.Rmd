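---
title: "Riemannian minimum-distance-to-mean decoding of oddball ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Riemannian minimum-distance-to-mean decoding of oddball ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riemerp)
```

## The decoding problem

In a K-command oddball brain–computer interface the user attends one of K
stimuli (tactile or auditory locations, for instance) while all K are
presented repeatedly in random order. The attended, rare stimulus evokes a
P300 — a positive event-related potential (ERP) deflection, typically
between 300 and 600 ms after onset — while the frequent unattended stimuli
do not. Decoding the attended command therefore reduces to deciding, for
each stimulus code, whether its epochs carry a P300.

Single-trial ERPs are buried in background EEG, so practical interfaces
average a small number of repetitions before deciding. The central
trade-off this package quantifies is **accuracy versus averaging depth**:
a classifier that reaches high accuracy with 1–5 averaged ERPs supports a
much faster interface than one that needs 10–15.

## The model

### Super-trial covariance features

Let a single epoch be the N × M matrix of N channels by M samples
(0–1000 ms after onset). Each trial is stacked with the **class
prototypes** — the averaged target and non-target epochs from the training
data — giving a 3N × M *super-trial*

$$X = \begin{bmatrix} X_{\text{trial}} \\ P_{\text{target}} \\
P_{\text{non-target}} \end{bmatrix},$$

with every row centred to zero mean. Its sample covariance

$$C = \frac{1}{M-1} X X^\top \in \mathbb{R}^{3N \times 3N}$$

is the classification feature. The prototype rows are identical for all
trials; what discriminates the classes is the *cross-covariance* between
the trial rows and the prototype rows — a target trial correlates with the
target prototype, a non-target trial does not. This compensates for the
weak spatial variability of ERP responses that makes plain N × N
covariances poorly discriminable.

Prototypes are always estimated on training folds and passed explicitly to
`build_super_trial()`, so a test trial can never leak into its own
prototype by construction.

### Riemannian geometry and the MDM rule

Covariance matrices are symmetric positive-definite (SPD) and live on a
curved manifold; Euclidean averages of covariances are systematically
biased toward "wide" matrices. The package uses the affine-invariant
metric

$$\delta_R(C_i, C_j) = \lVert \log(C_i^{-1} C_j) \rVert_F
 = \Big(\sum_n [\ln w_n]^2\Big)^{1/2},$$

with $w_n$ the eigenvalues of $C_i^{-1} C_j$. This distance is invariant
under congruence $C \mapsto W^\top C W$ for any invertible $W$ — i.e.
under any linear spatial mixing of the channels — which is what makes it
robust for EEG.

Training computes the per-class **geometric (Karcher) mean**

$$\bar C_k = \mathop{\arg\min}_{C}\sum_{j : l_j = k} \delta_R^2(C, C_j),$$

and the **minimum-distance-to-mean** (MDM) classifier assigns
$\hat l = \arg\min_k \delta_R(\bar C_k, C)$. Command selection scores each
stimulus code by
$\delta_R(C, \bar C_{\text{non-target}}) - \delta_R(C, \bar C_{\text{target}})$
and picks the arg-max (smallest code on a tie, for determinism).

### SWLDA baseline

The reference classifier is stepwise linear discriminant analysis, the
conventional P300 decoder: each epoch channel is decimated to 50 bins of
20 ms (mean amplitude), channels are concatenated (F = 50 N features), and
a forward-stepwise ordinary-least-squares regression on ±1 labels selects
features with entry threshold p < 0.10, removal threshold p > 0.15, and at
most 60 retained features — the de-facto defaults of the method. An empty
selection yields an intercept-only model that predicts the majority class.

## Numerical choices

* **Karcher mean iteration.** The mean is computed by the standard
  fixed-point iteration in the tangent space at the current estimate:
  initialise at the arithmetic mean and update
  $C \leftarrow C^{1/2}\exp\big(\frac1J\sum_j \log(C^{-1/2} C_j
  C^{-1/2})\big)C^{1/2}$ until the Frobenius norm of the tangent-space mean
  falls below 1e-8 (a log of eigenvalue ratios, hence scale-free) or 50
  iterations. Non-convergence — occasionally seen with very small,
  ill-conditioned training sets — returns the current estimate flagged
  `converged = FALSE` with a warning rather than an error, since a slightly
  unconverged centroid is still usable. All matrix log/exp/sqrt go through
  symmetric eigendecompositions with re-symmetrisation.
* **SPD regularisation.** Symmetry is checked at 1e-10 relative; sample
  covariances pass through `ensure_spd()`, which floors the spectrum at
  1e-10 × trace/d by diagonal loading so that rank-deficient covariances
  from short epochs cannot crash the pipeline. This loading policy is an
  implementation choice, not part of the published method.
* **Zero-phase filtering.** The 0.1–40 Hz band-pass is a cascade of
  4th-order Butterworth high- and low-pass sections applied
  forward–backward (zero phase, so the P300 latency is not shifted). A
  single band-pass transfer function with a lower edge at 0.1 Hz is
  numerically ill-conditioned at EEG sampling rates, hence the cascade.
  Each pass uses odd-symmetric end padding sized from the slowest filter
  pole (six time constants) and exact steady-state initial conditions, so a
  DC offset produces no edge transient.
* **Ties.** All arg-max/arg-min decisions break ties toward the smaller
  index; an SWLDA score of exactly zero is classified non-target.

## The synthetic oddball generator

No public recordings exist for the paradigms this package targets, so the
simulator is the primary test input. It reproduces the *structure* of a
spatial-oddball session:

* block-randomised schedules (each code once per sub-round,
  `reps_per_command` sub-rounds per block, one attended command per
  block), with onset spacing `stim_ms + isi_ms` — at 150 ms ISI
  consecutive 1000 ms epochs genuinely overlap, as in the real paradigms;
* a P300 modelled as a single positive Gaussian bump (defaults: 5 µV peak
  at 450 ms, 80 ms temporal SD) scaled by a smooth parieto-central scalp
  topography peaking at Pz, added only on attended-code events;
* background noise that is white Gaussian (4 µV) plus an independent 1/f
  component (4 µV) per channel, the first-order approximation of resting
  EEG spectra.

Defaults were fixed once from the stated paradigm descriptions (P300
positivity inside 300–600 ms; ordinary EEG background magnitudes) and the
preset table carries each scenario's command count, ISI, stimulus
duration, montage and sampling rate; where a scenario did not state a
timing or rate, the modal values of the remaining scenarios (150 ms,
100 ms, 512 Hz) are used.

What the generator deliberately does **not** model: spatially correlated
noise, trial-to-trial latency/amplitude jitter, artefacts (blinks, EMG),
non-target ERP components, and overlap of ERP responses from neighbouring
stimuli (the continuous route overlaps only the *noise*). Passing tests
therefore demonstrate correctness of the algorithms and the expected
qualitative behaviour (chance-level decoding without a P300, perfect
decoding at high SNR, accuracy growing with averaging, MDM's advantage
under small training sets) — not performance on real recordings.

## Evaluation protocol

The published evaluation reports accuracy per number of averaged ERPs
(k = 1..5) with pairwise rank-sum comparisons, but leaves the train/test
protocol unstated. `evaluate_accuracy()` uses 5-fold cross-validation over
selection blocks: per fold, prototypes and both classifiers are refit on
the training blocks only. Two further choices were genuinely open:

* **Training at matched depth.** For each k, training trials are averaged
  at the same depth as test trials, so both classifiers are fit on
  features with the test-time signal-to-noise. Fitting on single trials
  and testing on k-averages would hand the covariance classifier a
  systematic train/test distribution shift (averaging rescales the noise
  part of the covariance).
* **Aggregation.** Reported accuracies are mean ± SD over cross-validation
  folds (stated in the output metadata), with a two-sided Wilcoxon
  rank-sum p per k comparing the per-fold accuracies of the two
  classifiers. When every fold of both classifiers attains the same
  accuracy the rank-sum statistic has zero variance and the p-value is
  reported as 1.

Problem sizes used in the shipped tests and the acceptance script — e.g.
10-block sessions with 5 repetitions per command, 8 channels at 256 or
512 Hz, and 5–20 simulation seeds per property — were chosen as the
smallest sessions at which the statistical checks are well-powered.

## Known limitations

* The MDM implementation covers the two-class target/non-target case the
  command selector needs; it is not a general multi-class MDM.
* Only the affine-invariant metric is provided (no log-Euclidean or
  Wasserstein variants, no tangent-space vectorisation classifiers).
* The EDF writer/reader covers the plain continuous subset used here
  (identical rates, one-second records); EDF+ annotations are not parsed,
  and events travel in a tab-separated sidecar file with 0-based onsets.
* Stepwise OLS feature selection inherits the classical instabilities of
  SWLDA with tiny training sets; the implementation guards against
  enter/remove cycling and skips constant features, but with fewer trials
  than selected features the discriminant is necessarily degenerate —
  which is precisely the regime in which the covariance approach shows its
  advantage.
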