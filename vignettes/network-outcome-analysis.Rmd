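---
title: "Network outcome analysis: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network outcome analysis: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Baseline depression severity, summed over items of a rating scale, is a weak
predictor of treatment outcome. Individual symptoms carry different
information, but they are also strongly intercorrelated, so a symptom that
*marginally* predicts remission may do so only through its association with
other symptoms. Network outcome analysis (NOA) addresses this by estimating a
mixed graphical model (MGM) over all symptom items *plus* the binary outcome:
an edge between a symptom and the outcome node is then a conditional
dependence — a unique, direct predictive effect, controlling for every other
symptom. `noa` implements this pipeline for a 17-item clinician-rated
depression instrument (items scored 0–4, four items 0–2) and a 0/1 remission
outcome, together with the supporting machinery a full analysis needs:
a ground-truth cohort simulator, bootstrap stability analysis, a moderated
network model, odds-ratio translation of outcome edges, and baseline-table
statistics.

## The model and its estimation

Each symptom node is treated as continuous and regressed on all other nodes
by L1-penalized least squares; the outcome node is regressed on all symptoms
by L1-penalized logistic regression. Treating ordinal 0–4 items as continuous
is a deliberate, known-to-be-biased simplification: with cohorts of a few
hundred patients there are too few observations per response category to fit
categorical nodes, and no frequentist network model handles ordinal Likert
data directly. The bias is acknowledged rather than corrected.

The penalty `lambda` is selected *per node* by 10-fold cross-validation, at
the minimum of the mean out-of-fold error (squared error for symptom nodes,
deviance for the outcome node, whose folds are stratified by outcome so both
classes appear in every fold). The grid is log-spaced over 50 values from the
node's `lambda_max` (the smallest penalty that zeroes every coefficient) down
to `0.01 * lambda_max`. We use the CV minimum, not the one-standard-error
rule, because the target of the procedure is out-of-sample prediction error;
the consequences of that choice are discussed under *Limitations*.

Nodewise fits are combined into one network with the **AND rule** (default):
edge (i, j) is retained only when regression i keeps predictor j *and*
regression j keeps predictor i; its weight is the mean of the two
standardized coefficient magnitudes with their shared sign. Coefficients that
disagree in sign are kept at the mean magnitude and flagged sign-undefined.
The OR rule (either direction suffices; weight averaged over both positions,
so a lone 0.30 coefficient gives 0.15) is available but not the default — AND
is the conventional, more conservative choice for neighborhood-selection
graphical models. Because regularization can zero small true effects, the
model records its `smallest_retained_weight`: no conclusion should be drawn
about absent edges below that resolution.

**Predictability** is the proportion of a node's variance explained by all
other nodes: in-sample `1 - RSS/TSS` for symptom nodes, and for the outcome
node the accuracy of the nodewise classifier normalized against always
guessing the modal class; both floored at 0. It is computed in-sample because
one network is reported per cohort.

## Odds ratios

For a symptom with a retained outcome edge, the per-point odds ratio is
`exp(b)` where `b` is the symptom's *raw-unit* coefficient in the outcome
node's logistic regression — the multiplicative change in remission odds per
1-point item increase. The standardized combined weight decides edge
*presence*; the raw coefficient supplies the clinically interpretable OR.
Symptoms without a retained edge get OR exactly 1. ORs compound over score
differences (`or^k` for k points), and `cumulative_odds()` /
`percent_odds_change()` phrase them the way clinical reports do ("3.2 times
less likely", "the odds decreased by 25%"). Note that reporting-scale
rounding is applied *last*: an OR printed as 1.31 gives a 4-point fold of
2.9, while the unrounded coefficient behind it may give 3.0.

## Bootstrap stability

LASSO model selection replaces hypothesis testing, so edges come without
p-values. `bootstrap_network()` draws nonparametric case resamples (patients
with replacement, 500 by default), refits the entire pipeline on each with a
fresh deterministic fold assignment, and reports per-edge inclusion
proportions and percentile intervals (2.5/97.5 by default). These are
labelled **bCI** (bootstrapped confidence intervals) throughout: since
regularization shrinks every parameter — and every resampled parameter —
toward zero, the percentile intervals are *not* coverage-valid confidence
intervals and must be read descriptively. An outcome-adjacent edge that is
regularized away in a resample contributes OR = 1 to the OR distribution,
which is why unstable edges show bCI bounds of exactly 1. Resamples in which
only one outcome class survives are skipped and excluded from `n_effective`
(at a 62% remission rate and n = 161 this is vanishingly rare). Case
resampling, rather than residual resampling, is the natural unit for
cross-sectional cohort data; bias-corrected interval variants are omitted
because the distributions are explicitly descriptive.

## Moderation

To test whether a binary grouping variable (study membership, here) changes
any pairwise relation, `estimate_moderated_network()` augments every
nodewise regression with the moderator main effect and all
predictor-by-moderator product terms under one jointly penalized fit. The
products are built on standardized predictors while the 0/1 moderator is left
unstandardized, so an interaction weight reads directly as a between-level
difference in standardized edge weight. A pair is reported as moderated when
its interaction term survives the configured edge rule. An empty result is
non-detection — absence of evidence, never evidence of absence. One moderator
at a time, binary only; whether the original analyses shared one penalty
between main and interaction terms is not documented, and a shared per-node
penalty is used here.

## The synthetic-cohort generator

Real patient cohorts of this kind are not publicly deposited, so the package
ships a generator that runs the estimation model class forwards — making
parameter recovery a well-posed test:

* **Latent symptoms**: a conditional-Gaussian pairwise model. Node i's full
  conditional is normal with mean `intercept_i + sum_j w_ij x_j` and shared
  `residual_sd` (1 by default; per-item spread is carried by the network
  structure). The implied precision matrix `(I - W)/sd^2` must be positive
  definite, checked at construction — an improper model fails fast, never
  diverges silently.
* **Sampling**: single-chain Gibbs, one retained state per patient after a
  burn-in of 200 sweeps and thinning of 5 (defaults chosen so the lag-1
  autocorrelation of retained chains stays below 0.2 for the models used in
  the tests).
* **Outcome**: Bernoulli with `logit p = intercept + sum_i beta_i x_i`
  applied to the patient's latent values.
* **Moderator**: Bernoulli(0.5) per patient — mimicking two roughly
  equal-sized trials — switching the weight matrix (and optionally the
  outcome coefficients) by additive shifts for that patient's sweeps.
* **Discretization**: each latent value is mapped affinely from
  `[mu - 2.5 sd, mu + 2.5 sd]` (base-level marginal moments) onto the item's
  0–4 or 0–2 range, rounded and clipped, which keeps all response categories
  populated without gross imbalance.

`default_paper_like_model()` is the reference truth used across the test
suite: 17 items with a sparse, clinically organised symptom network
(mood/guilt/suicidality triangle, insomnia triad, anxiety chain, somatic
cluster; edge weights around 0.1–0.25, jittered by seed) and exactly three
nonzero outcome coefficients — `log 0.75` on suicidality, `log 1.21` on
retardation, `log 1.31` on hypochondriasis — with the intercept set for a
remission rate near 62%. The symptom-symptom edge weights are free
parameters of the simulator, not published estimates; only the outcome
structure mirrors reported findings. The generator emulates conditional
dependence, ordinal discreteness and outcome prevalence; it does **not**
emulate item-level missingness, floor effects of severely skewed items,
rater effects, or longitudinal change, so passing recovery tests here shows
the estimator works for the assumed data-generating class, not that real
cohorts satisfy those assumptions.

## Numerical choices and degenerate inputs

* Fold assignments are seeded from `cv_seed` *and the node label*, so a fixed
  seed yields identical folds and selected penalties, and permuting item
  columns permutes the estimate exactly.
* Constant predictor columns are excluded from a regression with a warning
  (coefficient 0); an outcome node with one class is an error.
* Unregularized fits (`lambda = 0`) are computed along a warm-started path
  with a tight convergence threshold and match textbook least-squares /
  maximum-likelihood fits to 1e-4 / 1e-3.
* Zero-variance nodes have predictability 0 by definition; predictability is
  clamped to [0, 1].
* An empty network has `smallest_retained_weight = NA`.
* Degenerate bootstrap resamples are skipped, not errors; `n_boot = 1` yields
  0/1 inclusions and point intervals.

## Problem sizes used by the test suite

Monte-Carlo checks run at the generator's study conditions: cohorts of
n = 2000 for oracle-equivalence, recovery (20 replicates) and null
false-positive studies (100 replicates), 200 bootstrap resamples for
stability, and 50 replicates each for the moderation null (n = 2000) and a
+0.5 shifted edge (n = 4000). These sizes give Monte-Carlo standard errors
comfortably below the margins being tested.

## Known limitations

* **CV-minimum selection over-selects under the null.** Choosing `lambda` at
  the CV-error minimum targets prediction, not support recovery; with
  cross-validation noise the selected penalty frequently sits below
  `lambda_max` even when no true edges exist, so small spurious edges — and,
  in the moderated model, small spurious interaction pairs — survive the AND
  rule in a substantial fraction of null datasets. The package reports edge
  stability (bootstrap inclusion proportions) precisely so that such fragile
  edges can be recognised; a one-standard-error selection rule would be more
  conservative but is not what this pipeline specifies.
* Ordinal items are modelled as continuous (see above).
* bCIs are descriptive, not inferential.
* In-sample predictability is optimistic for weakly connected nodes.
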