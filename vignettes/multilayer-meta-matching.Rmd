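---
title: "Multilayer meta-matching: models, protocol, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer meta-matching: models, protocol, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Predicting a phenotype (a cognition score, a health attribute) from a
participant's resting-state functional connectivity (RSFC) is
statistically brutal in the usual small-study setting: the feature is a
P × P correlation matrix — 87,571 edges at P = 419 — while the study has
tens to hundreds of participants. Large population datasets exist, but they
measured *different* phenotypes. Meta-matching exploits the observation that
phenotype batteries are correlated through shared latent dimensions: a model
trained to predict many source phenotypes in large datasets can be
*translated* to a new target phenotype using only K labelled target
participants (K-shot adaptation), by using the source models' predictions as
a low-dimensional feature space.

`metamatchr` implements the full translation stack for the multi-source
case, where the source datasets have very unequal sizes, plus the baselines
it must be compared against, an evaluation protocol, and feature-importance
tooling.

## Models

**Feature space.** Each participant's symmetric FC matrix is vectorized to
its strict lower triangle in row-major order (`vectorize_lower_triangle()`),
the canonical edge order used everywhere, including importance maps and
serialization. Cross-dataset learners consume per-participant normalized
vectors: subtract the mean, divide by the L2 norm of the demeaned vector, so
the result has exactly zero mean and unit norm and the operation is
idempotent. Whether the norm is taken before or after demeaning is a
convention; we adopt the demeaned-norm reading because it makes the
correlation kernel equal the plain dot product on normalized vectors and
normalizing twice a no-op. Normalization exists because preprocessing
pipelines differ in where they center FC values (global-signal regression
centers them at zero; other pipelines do not); it provably does not affect
correlation-kernel KRR, and the package tests that claim directly.

**Kernel ridge regression (KRR).** The kernel between two participants is
the Pearson correlation of their feature vectors. Fitting solves
`(K + lambda I) alpha = y - mean(y)` on the participants with an observed
target; the target mean is added back at prediction (a correlation kernel
has no intercept pathway, so targets are centered — a documented choice).
`lambda` is tuned by 5-fold cross-validation over a logarithmic grid
(0 plus 20 points from 1e-4 to 1e4), scoring mean squared validation error
and breaking ties toward the *larger* lambda — preferring stronger
regularization in the small-sample regime this tool targets. The final
model is refit on all provided participants with the chosen value.

**Linear ridge regression (LRR).** One model per source phenotype, with an
unpenalized intercept (fitted by centering), the same grid/CV/tie rules,
missing targets dropped row-wise. Internally both ridge solvers
eigendecompose the smaller Gram matrix (features-by-features or
participants-by-participants, whichever is smaller) once per fold and reuse
it across the entire lambda grid.

**Multi-output network.** The extra-large source dataset also trains a
fully connected ReLU network predicting all its phenotypes at once from the
normalized FC vector, minimizing *masked* mean squared error: missing
phenotype cells contribute nothing to loss or gradient. Targets are
z-scored per phenotype with training-split statistics (predictions are
de-standardized on output) so the joint loss weights phenotypes equally.
Defaults: hidden layers 256/128/64, dropout 0.3, Adam at 1e-3, batch 128,
at most 100 epochs with early stopping (patience 10) on the 20% validation
split. These are reasonable defaults for the architecture, all overridable
via `mlp_config()`; initialization and the shuffle/dropout stream use
separate derived seeds so that a change in output-layer width cannot
perturb the training trajectory of shared parameters.

## The translation strategies

Source datasets are grouped by size class: *extra-large* (network + LRR
per phenotype, trained on its 80/20 split), *large* and *medium* (LRR per
phenotype, tuned and refit on the full dataset). Given K target
participants with one observed target phenotype:

- **Meta-matching with stacking** (single source): the extra-large
  network's predictions (T_xl columns; optionally both families, 2·T_xl)
  become features for a correlation-kernel KRR meta-learner fit on the K
  participants. All columns are always used; there is no feature
  truncation at small K.
- **Meta-matching with dataset stacking**: concatenates the extra-large
  predictions (2·T_xl) with every other dataset's direct LRR predictions —
  `2*T_xl + sum(T_other)` columns (296 in the 67/36/23/42/61 reference
  configuration).
- **Multilayer meta-matching**: before the final stacking, each large
  dataset's phenotypes are *re-predicted* by stacking models trained on the
  extra-large predictions over the full large dataset; each medium
  dataset's phenotypes likewise from extra-large + large-LRR predictions.
  Each non-extra-large dataset therefore contributes its direct and its
  stacked predictions — `2*T_xl + 2*sum(T_other)` columns (458 in the
  reference configuration). Intermediate stackers are trained on the full
  corresponding dataset (no inner K-shot), which makes maximal use of the
  small datasets.

Stacking feature columns are z-scored with the stacking-training-sample
statistics before the correlation kernel, stored in the model and reapplied
at prediction. Base-learner predictions live in heterogeneous phenotype
units; without column scaling the row-correlation kernel would be dominated
by large-unit columns. This is the package's choice and is deliberately
invariant to permuting columns together with their labels.

**Transfer learning baseline.** The pre-trained network's output layer is
replaced by a freshly initialized single output; only the last two layers
(final hidden + output) are updated — "last two layers" read as parameter
matrices, the natural interpretation. A fixed learning rate is chosen by
5-fold CV and grid search on the K participants; the final finetune uses
all K with an 80/20 early-stopping split, a 10-epoch cap and patience 3
(the cap is prescribed; the patience and the Adam optimizer are documented
defaults). Dropout is disabled during adaptation (K is tiny).

## Evaluation protocol

For each K in {10, 20, 50, 100, 200}, each repetition draws K participants
with the target observed; models adapt on those and are scored on the
remaining N − K by Pearson's r and predictive COD,
`1 - SS_res / SS_baseline`, where the baseline is the *K-shot sample mean*
— the natural reference an adapted model must beat, and a documented
convention since the metric admits variants. Undefined metrics (constant
predictions, fewer than 3 evaluation pairs) are recorded as missing and
excluded from means with counts kept, never silently zeroed. All approaches
see identical splits (paired design), and approaches receive target values
only for the shot participants, which makes evaluation-set leakage
structurally impossible. Aggregation averages over repetitions within
phenotype, then across phenotypes.

Two approaches are compared by a paired bootstrap on the per-(phenotype,
repetition) metric differences: phenotypes are resampled with replacement
and repetitions within each sampled phenotype; the two-sided p-value is
`2 * min(P(mean <= 0), P(mean >= 0))` with a +1 continuity floor. The exact
published recipe is not available, so this documented procedure — which
respects the paired structure and the phenotype-averaged headline metric —
stands in; its null calibration is tested (p-values approximately uniform
under identical generating processes). Benjamini–Hochberg FDR is applied
once over the pooled family: all K values, all approach pairs, both
metrics.

## Haufe-transform importance

A predictive model is interpreted through the covariance of each FC edge
with the model's *prediction* across participants (unbiased, n − 1
denominator; agreement correlations are denominator-invariant anyway).
Positive importance: higher connectivity at that edge pushes the
prediction up. The pseudo ground truth trains correlation-kernel KRR on
the full target sample and Haufe-transforms its in-sample predictions —
in-sample rather than cross-validated, the straightforward reading of a
full-sample reference map. Approach-level maps at K use the K adaptation
participants only.

## The synthetic suite

Real inputs for this problem are access-controlled, so the package ships a
latent-factor generator (`simulate_collection()`). Shared latent factors
`z` (length L) drive the features, `x = A_d z + shift + noise`, with `A_d`
blending a common core and a dataset tilt (0.3); each phenotype loads
`c = cross_loading_strength` on a canonical direction from a pool shared by
all batteries and `sqrt(1 - c^2)` on dataset-unique latent factors the
features cannot see. Consequences worth stating: at `c = 0` nothing
transfers; at `c = 1` with zero noise targets are exactly linearly
recoverable; for `0 < c < 1` the unique component bounds attainable
accuracy below 1 — mirroring the unpredictable variance every real
phenotype carries.

`default_suite()` instantiates the canonical study: five sources with
N = 4000/1500/300/300/300 and T = 20/12/8/8/8 phenotypes (one extra-large,
one large, three medium), a 600-participant target with 10 phenotypes,
P = 40 parcels (780 edges), L = 6, `c = 0.7`, 10% source missingness, and
alternating feature shifts (0/0.4) emulating mixed preprocessing. Noise
levels are calibrated to the regime that makes K-shot translation a
meaningful problem: feature noise sd 3 puts each edge's signal fraction at
`1/(1 + 3^2)` = 10%, matching the small edge-level effect sizes typical of
FC data — individually weak edges whose information must be pooled, which
is precisely what source-trained models can do and a K = 100 ridge model
cannot; phenotype noise sd 1 caps predictability near r = 0.5, about where
real phenotype prediction tops out. With cleaner features the simulation
leaves the regime the method exists for: a 100-participant kernel model
already saturates the ceiling and translation has nothing to add.

What the generator does *not* emulate: realistic fMRI noise spectra, head
motion, site/scanner covariance, informative missingness, non-linear
latent-phenotype links. Passing the suite shows the machinery ranks methods
as expected where transferable structure exists by construction — not that
it will do so on any particular real cohort.

## Numerical and protocol choices

- Symmetry tolerance for FC input: `max |M - t(M)| <= 1e-8`; FC matrices
  are correlation matrices, larger asymmetry indicates an upstream bug.
- Singular kernel systems at `lambda = 0` raise an error advising
  `lambda > 0` when fit directly; during CV they simply score as
  non-candidates.
- Eigenvalue floors (1e-10 relative) guard the shared-eigendecomposition
  solver against negative round-off eigenvalues.
- Fold assignment is a uniform random permutation — deliberately so, no
  demographic matching, replayable from the seed.
- One top-level seed fans out to every stage through
  `derive_seeds()` (a seeded draw of child seeds), which is what makes two
  full CLI runs byte-identical.
- Containers are plain text: CSV at 17 significant digits (lossless for
  doubles) for datasets; JSON with base64-encoded IEEE-754 payloads for
  models, so a save/load round trip reproduces predictions bit-identically.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script runs use the default suite (780
edges, 6200 simulated participants across datasets) with 20 repetitions at
K = 100 and K = 10; the importance-agreement check runs 50 repetitions on
one target phenotype; the reference-configuration feature-count check
trains the 67/36/23/42/61 battery at small n (80/50/40/40/40 participants,
28 edges), since the column bookkeeping depends only on the battery sizes.
These sizes keep a full run in minutes on one CPU while leaving every
statistical assertion comfortably powered.

## Known limitations

- Exactly one extra-large dataset is supported per hierarchy (the cascade
  is defined relative to it); multiple extra-large sources would need a
  defined ordering among them.
- The "meta-matching finetune" variant and deeper-than-three-layer
  cascades are out of scope.
- Intermediate stackers inherit whatever bias the extra-large models carry
  toward their own battery; nothing corrects for that beyond the final
  stacking step.
- The bootstrap comparison and the COD baseline are documented conventions
  (see above), not reproductions of an external specification.
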