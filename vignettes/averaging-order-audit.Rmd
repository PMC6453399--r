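---
title: "Auditing trial-averaged statistics and chance-level claims in yes/no hemodynamic experiments"
author: "trialaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing trial-averaged statistics and chance-level claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialaudit)
```

## The problem

In trial-based "yes"/"no" communication experiments with functional
near-infrared spectroscopy (fNIRS), a patient answers known-truth-value
questions while relative oxygenated-hemoglobin (HbO) changes are
recorded on many optical channels. The data are organized as
patient → day → session → condition → trials × channels × timepoints.
Two statistical questions decide whether communication happened:

1. Does the average hemodynamic response differ between "yes" and "no"
   questions at any timepoint?
2. Can a classifier decode the answer from single trials at an accuracy
   significantly above chance?

Both questions are easy to get wrong in ways that produce confident
false positives. This package implements the analyses together with the
audits that expose those failure modes, and a synthetic data generator
that reproduces the statistical structure of such recordings so every
stage can be tested end to end.

## Averaging order decides the replicate unit

Before a timepoint-wise *t*-test, the trial × session × channel data
must be collapsed to one set of replicate curves per condition. The
arithmetic of the mean makes the *order* of collapsing irrelevant for
the grand mean (in balanced designs) — but not for the variance:
whichever axis survives supplies the variance the *t*-test uses.

* **Method A ("A-flawed")** averages over trials, then over sessions;
  the surviving replicates are the **channels**. fNIRS channels overlap
  optically and hemodynamically and are highly correlated, so their
  across-channel scatter wildly understates the uncertainty of the
  condition means. The test is anticonservative: on pure-noise data with
  channel correlation 0.95 it declares the vast majority of timepoints
  "significant".
* **Method B ("B-correct")** averages over channels, then over trials
  within each session; the surviving replicates are the **sessions**,
  which are genuinely independent recording units. The test is
  calibrated: its false-positive rate matches the nominal level.

`collapseDataset()` implements both orders with stagewise *unweighted*
means (so unbalanced designs may give slightly different grand means
between orders — the equivalence is asserted only for balanced designs),
`timepointTTest()` runs the per-timepoint test, and `compareMethods()`
produces the side-by-side report that `renderMethodComparison()` turns
into a two-panel mean-±-SD figure with significant timepoints shaded.

The default test is the unpaired pooled-variance Student *t*; Welch and
paired variants are exposed by flags because the exact variant used in
published analyses of this kind is rarely stated. Multiple-comparison
correction defaults to `"none"`, deliberately mirroring the uncorrected
practice under audit; Bonferroni and Benjamini–Hochberg are available.
Averaging across channels at all is itself questionable — a localized or
sign-varying effect can cancel in the channel mean — so
`channelwiseTTest()` also provides the per-channel analysis (sessions as
replicates, optional correction applied jointly across channels ×
timepoints).

### Degenerate inputs

Noiseless synthetic fixtures hit zero replicate variance. The rules
are explicit rather than library-dependent: zero pooled variance with
equal means gives *t* = 0, *p* = 1; zero variance with unequal means
gives *p* = 0 and a degenerate-timepoint flag plus a warning (not an
error); fewer than two replicates per condition is an error.

## The permutation validity audit

A statistical procedure applied to labels that were randomly reassigned
should find nothing. `permuteLabels()` reassigns trials to conditions
within each session, preserving per-session condition counts (the
conservative choice that respects session structure; a global scope is
available behind a flag), and `permutationAudit()` reruns
permute → collapse → test, flagging a permutation when any timepoint
falls below the audit threshold (default 0.0005, the conventional
display threshold for such masks; configurable). Per-permutation seeds
are derived from the master seed and the permutation index, so audits
are reproducible and permutations independent.

On highly correlated null data Method A is flagged in essentially every
permutation while Method B is flagged at roughly the rate expected by
chance alone. That baseline rate is worth stating precisely: with
`T` effectively independent timepoints a *valid* procedure still flags a
permutation with probability `1 − (1 − 0.0005)^T` — about 0.095 for
`T = 200`. A small audit (10 permutations) of a correct method will
therefore occasionally show one or even two flagged permutations without
indicating any defect; the diagnostic signal is the *separation* between
the two orders, not a zero count for the correct one.

## Decoding and the chance level

`runOfflineReanalysis()` reproduces the offline decoding pipeline: one
linear SVM per day, 10-fold stratified outer cross-validation, training
folds balanced by randomly undersampling the majority class
(`balanceByUndersampling()`), and the regularizer C selected per outer
fold by an inner 10-fold grid search over `10^(-3..3)` on the balanced
training data only (smallest C among the maximizers, preferring stronger
regularization deterministically). Held-out blocks are never balanced
and never touch model selection; the package tests this leakage guard
explicitly by mutating held-out labels and checking that neither the
selected C nor the decision values move. Correct/total counts are pooled
over folds — a binomial assessment needs counts, not a mean of fold
accuracies.

Outer folds are stratified by class although plain random splitting is
the more common description; on small days stratification prevents
degenerate single-class test blocks and is declared rather than silently
assumed. The feature representation defaults to per-channel window
means: the mean over a response window minus the mean over the
pre-stimulus baseline. The response window default is (3, 8) s —
approximately the full width at half maximum of the canonical
double-gamma hemodynamic response, which peaks near 5 s (half-maximum
crossings at 2.81 s and 8.07 s) — and the baseline window is (−5, 0) s.
A full-timecourse representation is available behind a flag.

`accuracyBinomialTest()` supplies the exact binomial tail probability of
`k` correct out of `n` against chance (one-sided "greater" by default,
matching the directional claim "above chance"; no normal approximation),
with a Clopper–Pearson interval. The companion
`minTrialsForSignificance()` quantifies the small-sample critique of
accuracy claims: 8/10 correct — 80% decoding — has `p = 0.0546875`
against a fair coin, and even *perfect* decoding needs 5 trials to reach
`p < 0.05`. Ten-trial accuracy claims carry almost no statistical
weight.

### The SVM solver

The linear SVM (hinge loss, L2 penalty, cost C) is fit by dual
coordinate descent with shrinking — the standard algorithm for linear
SVMs, which maintains the weight vector explicitly so the cost of a
sweep is independent of C. The general-purpose SMO solvers behind the
usual R interfaces require iteration counts that grow roughly linearly
in C on non-separable data, which makes a 10 × 10 × 7-point nested grid
search over `10^(-3..3)` impractically slow at the upper grid end; a
dedicated linear solver is what the field's decoding toolchains use for
exactly this reason. Tolerance (0.1 on the projected-gradient gap) and
the sweep cap (1000) are pinned at the conventional defaults of this
solver family; fits at extreme C on noise may stop at the cap, exactly
as those toolchains do, which at most depresses the inner-CV score of a
C value that would not have been selected anyway. The intercept rides on
an augmented constant feature and is therefore lightly regularized. The
solver is deterministic (fixed internal shuffling sequence), and the
test suite cross-checks it against an independent SMO implementation
(e1071/libsvm) where both converge.

## The synthetic generator

`generateDataset()` draws trial data from an explicit generative model:
per trial, channel *c* and epoch time τ,

x(τ, c) = β · h(τ) · g_c · [condition = yes] + σ_sh · z(τ) + σ_ch · ε_c(τ) + d_c(τ)

* `h` — canonical double-gamma hemodynamic response (peak delay 6 s,
  undershoot delay 16 s, dispersions 1 s, undershoot ratio 1/6),
  normalized to peak 1, `hrf()`;
* `β` (`effectAmplitude`) — condition-locked response amplitude,
  entering "yes" trials only (the simplest separable structure; the
  analyses only use the difference), with optional per-channel gains
  `g_c`;
* `z` — a latent process shared by all channels, white in time (temporal
  autocorrelation is carried by the drift term, keeping the two knobs
  orthogonal), scaled by `σ_sh`;
* `ε_c` — independent channel noise, `σ_ch`;
* `d_c` — optional stationary AR(1) drift per channel (coefficient φ,
  innovation sd `σ_d`), drawn fresh per trial.

The implied inter-channel correlation is
ρ = σ_sh² / (σ_sh² + σ_ch² + σ_d²/(1 − φ²)) (`channelCorrelation()`).
The epoch grid covers the half-open window `[start, end)` at the
sampling rate — e.g. (−5, 20) s at 8 Hz gives exactly 200 samples — and
must include a pre-stimulus baseline (`start < 0`). Generation is
bit-reproducible given the configuration, including its seed.

### Presets and the effect calibration

* **`null-highcorr`** — β = 0, 20 channels at ρ = 0.95
  (σ_sh² = 0.95, σ_ch² = 0.05), 1 day × 10 sessions × 10 trials per
  condition, 200 timepoints. The sampling rate and epoch window of the
  motivating recordings are not published; 8 Hz over (−5, 20) s is a
  stand-in chosen once and stated here.
* **`effect-strong`** — the same noise structure over 4 days ×
  10 sessions, with β = 0.443389 calibrated so the Bayes-optimal
  single-trial accuracy of the generative model is 0.9. With uniform
  loadings and white shared noise the optimal discriminant reduces to
  the channel mean followed by a matched temporal filter, so the
  Mahalanobis separation is d(β) = β · sqrt(Σ_τ h(τ)² / (σ_sh² + σ_ch²/C))
  and β solves Φ(d/2) = 0.9 on the 200-point grid. The test suite
  verifies the frozen value against `bayesAccuracy()`, a Monte-Carlo
  implementation of the likelihood-ratio rule (drift-free configurations
  only, where the per-timepoint whitening is exact).
* **`imbalanced`** — `null-highcorr` with 7 yes / 3 no trials per
  session, to exercise the undersampling logic.

A window-mean decoder cannot reach the Bayes accuracy: averaging the
response window trades the matched filter for a flat one, and baseline
subtraction adds baseline noise. With the FWHM response window the
asymptotic accuracy of the best linear read-out of window-mean features
on `effect-strong` is ≈ 0.80, which is what a well-functioning pipeline
should approach from below — hence the effect-recovery check asks for
≥ 0.75 pooled over 800 trials, most of the available separability.

### What the generator does and does not emulate

It reproduces the *statistical* structure the audits depend on:
condition-locked responses, strong inter-channel correlation,
session/day grouping, unequal per-condition counts, pre-stimulus
baselines, optional slow drift. It does not attempt physiological
realism: no Mayer waves, no motion artifacts, no deoxygenated-hemoglobin
channel, no heterogeneous per-channel noise, no non-stationarity across
sessions. Passing tests on synthetic data therefore demonstrate that the
*procedures* behave as claimed under the stated model — not that any
particular real recording satisfies that model.

## Numerical and design choices

* Stagewise means are unweighted at every stage; both averaging orders
  and their difference in retained variance follow from that single
  rule.
* Time axes are validated to be strictly increasing and uniform within a
  relative tolerance of 1e-9, and CSV time stamps must match the
  manifest's authoritative axis within 1e-9 s (the manifest stores the
  axis once; per-row floats are a consistency check, not a source of
  truth).
* Trial and channel indices in the interchange CSVs are 0-based and
  contiguous per session and condition; condition labels are exactly
  `yes`/`no`.
* Seeds: every seeded operation derives child seeds from a master seed
  and a counter through a fixed 32-bit linear-congruential mix, so
  permutations, folds and balancing draws are independent,
  reproducible, and never perturb the caller's RNG state.
* Inner-CV ties on C are broken toward the smallest (most regularized)
  maximizer.
* The fold count falls back to the minority-class count (with a warning)
  when a day is too small for 10 stratified folds.

## Problem sizes used by the test suite

The packaged checks run on one CPU in a few minutes: a 20-seed panel of
`null-highcorr` datasets for the type-I and audit separations, 20 seeds
of 400-trial pure-noise decoding for null calibration of the nested CV,
5 seeds of `effect-strong` (800 trials each) for effect recovery, and
10⁴-draw enumerations for the exact small-sample checks. These sizes are
the package's definition of its evidence; larger panels sharpen nothing
qualitative.

## Limitations

* No hierarchical/mixed-effects models and no cluster-based permutation
  statistics; both are better practice for real timepoint-wise inference
  and are deliberately out of scope here, where the goal is to audit the
  procedures actually in dispute.
* The audit's any-timepoint flag is intentionally simple (no max-T or
  cluster correction); see the base-rate caveat above.
* `bayesAccuracy()` covers drift-free configurations only.
* The exchangeability check in the test suite uses a single-channel null
  configuration: with multiple correlated channels the pooled-sample
  Kolmogorov–Smirnov test's iid assumption fails by construction, so the
  nominal-rate claim is only well-posed for the single-channel fixture.
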