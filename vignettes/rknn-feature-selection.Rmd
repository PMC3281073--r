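---
title: "Random KNN feature selection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random KNN feature selection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rknnfs)
```

## The model

Random KNN is a random-subspace ensemble in the spirit of Random Forests,
with k-nearest-neighbour base learners instead of trees. Given an `n x p`
training matrix with class labels, each of `r` base classifiers draws `m`
of the `p` features uniformly without replacement and classifies by
majority vote of the `k` nearest neighbours under Euclidean distance
restricted to those features. The ensemble prediction is the majority of
the `r` base votes. Two properties follow directly and are enforced by
tests: with `m = p` every base classifier is the same full-feature KNN, so
the ensemble degenerates to plain KNN; and since KNN is stable, no
bootstrap resampling of the cases is performed — subspaces are the only
source of diversity.

The method assumes a meaningful Euclidean geometry on the features. It is
distance-based, so features on wildly different scales will dominate the
metric; `zscore_dataset()` offers explicit per-feature standardisation,
default off, and the choice is recorded in the run metadata. Missing
values are rejected rather than imputed, so any imputation is a visible,
separate preprocessing decision.

### Feature support

For feature scoring, each base classifier measures its own accuracy: the
samples are partitioned into a base half (`ceiling(n/2)`) and a query half,
the query half is classified against the base half inside the classifier's
subspace, and the fraction correct is recorded. Crediting that accuracy
back to each of the `m` participating features gives the *support* of a
feature: its mean accuracy over the base classifiers containing it. This
is bidirectional voting — features vote for labels, and classification
results vote back for features. The bookkeeping identity

  sum_f M(f) * support(f) = m * sum_i acc_i,

with `M(f)` the number of classifiers containing `f`, holds exactly up to
floating-point rounding and is asserted in the test suite on every
configuration exercised; likewise `sum_f M(f) = r * m`.

Two partition modes exist. The *dynamic* mode (default) redraws the
base/query split for every base classifier, which decorrelates the
accuracy measurements; the *fixed* mode draws one split per run and shares
it, which is useful when a single common test bed is wanted. A feature
that lands in no subspace has undefined support and is reported as `NA`,
never as 0 — a zero would falsely mark it maximally irrelevant. With the
defaults (`r = 2000`, `m ≈ √p`) the expected multiplicity `r·m/p` is large
enough that undefined supports are rare.

### Two-stage backward elimination

RKNN-FS applies the support ranking recursively. The geometric stage drops
a proportion `q` of the lowest-ranked features per iteration, running

  ni = floor( ln(min_dim / p) / ln(1 - q) )

iterations with `min_dim = 4` by default; the retained count follows
`p_next = ceiling(p * (1 - q))`. The ensemble mean accuracy (the average
of the `r` base-classifier accuracies) is recorded per iteration, and the
iteration *before* the accuracy maximum — the pre-max iteration — hands
its feature set to the linear stage, a conservative choice that keeps the
larger of the two candidate sets. The linear stage then drops `d` features
(default 1) at a time for `floor((p_start - min_dim) / d)` steps and
returns the set with maximal ensemble accuracy.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 3 | neighbours per base KNN; small values (1 or 3) suit `n ≪ p`, where only near neighbours are informative |
| `r` | 2000 | base classifiers; accuracy saturates beyond roughly 1000, 2000 adds stability headroom for support estimates |
| `m` | `round(√p)` | subspace size; the square-root rule maximises dissimilarity between random subsets |
| `q` | 0.2 | geometric-stage drop proportion; smaller is safer and slower |
| `d` | 1 | linear-stage drop count |
| `min_dim` | 4 | floor on the retained feature count |
| `partition_mode` | dynamic | per-classifier base/query resplit for classifier diversity |
| `seed` | none | master seed; fixes every subset, partition, and hence every output byte |

All quantities are unitless (expression values enter only through
Euclidean distances).

## Numerical and tie-breaking choices

Determinism everywhere was a design goal: with a fixed seed, supports,
traces and cross-validation results are byte-identical across runs.
The choices that make that possible:

- **Distance ties** at the k-th neighbour are resolved by sample
  identifier (ascending), so the neighbour set is unique and independent
  of row order.
- **Vote ties** (base KNN and ensemble alike) go to the first label in
  canonical sorted order.
- **Support ties** in the ranking are broken by higher multiplicity, then
  by feature (column) order.
- **Accuracy-argmax ties** across elimination iterations keep the earliest
  iteration, i.e. the larger feature set — the conservative option.
- **`ni` rounding**: the iteration-count formula is floored, so the
  schedule never undershoots `min_dim`; the retention rule is a ceiling,
  which only drops a feature when `q·p ≥ 1`, and an explicit guard stops
  the stage if a step would stall or fall below `min_dim` (exercised at
  adversarial small `p`/`q` in the tests).
- **Pre-max clamp**: when the accuracy maximum is already the first
  iteration, "the iteration before it" is undefined and clamps to
  iteration 1.
- **Odd `n`**: the base half receives the extra sample, giving the
  neighbour search the larger pool.
- **`m` during elimination**: under the default rule `m` is recomputed as
  `round(√p)` from the *current* feature count each iteration (keeping
  subset diversity maximal as `p` shrinks); an explicit `m` is capped at
  the current `p`.
- **Per-fold seeds** in external LOOCV are derived from the master seed by
  a splitmix-style integer mix (`derive_seed`), so folds are mutually
  independent streams yet reproducible in any order.
- **Standard deviations** in stability summaries are sample (n−1)
  standard deviations, the convention for small-replicate summary tables;
  the coefficient of variation is reported ×100.

Degenerate inputs are handled explicitly: datasets with one class, missing
values, or duplicate identifiers are rejected at construction; `p ≤
min_dim` skips elimination and returns all features; a LOOCV fold that
would empty a class is skipped with a warning and accuracy is computed
over the evaluated folds.

## The synthetic test bed

Real microarray benchmarks are external downloads, so the package carries
its own generator, `synthetic_dataset()`, whose defaults emulate the
published regime: `n` in the tens-to-hundreds, `p` in the thousands, 2–26
classes, optionally unbalanced, with a small planted subset of informative
features. Noise features are independent standard normals; each planted
feature receives class means on a centred grid of spacing `shift` (in
noise-sd units). At `shift = 1.5` and 10 planted features, the classes are
well separated in the planted subspace (plain 3-NN on the planted features
alone exceeds 0.85 leave-one-out accuracy), which is the difficulty the
recovery experiments are calibrated against; `shift = 0` is an exact null.

The generator deliberately omits features of real expression data — probe
effects, batch effects, heavy tails, correlated gene modules,
heteroscedastic noise. Passing the recovery tests therefore demonstrates
that the implementation ranks and selects as specified under clean
Gaussian signal; it does not by itself establish performance on real
microarray data.

## Problem sizes used by the tests

The test and acceptance workloads are scaled to desk size as the package's
own test design: oracle equivalence on hundreds of random instances with
`n ≤ 50`, `p ≤ 20`; recovery experiments at `n = 60`, `p = 500`, 10
planted features, `r = 2000`, five replicate seeds; support-gap
monotonicity over shifts {0, 0.5, 1.0, 1.5} with five seeds per shift; and
external LOOCV demonstrations at `n ≤ 30`, `p ≤ 100` with smaller
ensembles. The full suite runs in a few minutes on one CPU.

## Known limitations

- Only unweighted majority voting is implemented; distance-weighted votes
  are not offered.
- The distance metric is fixed to Euclidean.
- Regression-mode Random KNN is out of scope; the package is
  classification-only.
- `m`, `q` and `d` are not tuned automatically.
- The ensemble kernel is single-threaded; `r` base classifiers are cheap
  (`O(r · m · n²/4)` per support computation) but very large `p` with the
  linear stage enabled can be slow — the `stage1_only` option mirrors the
  common benchmarking shortcut of stopping after the geometric stage.
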