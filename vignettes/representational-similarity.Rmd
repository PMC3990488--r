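---
title: "Representational similarity analysis with repsim: models, inference, and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representational similarity analysis with repsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repsim)
```

## The model

Representational similarity analysis (RSA) characterizes a neuronal
population code not by its individual response channels but by its
*representational geometry*: the matrix of pairwise dissimilarities between
the activity patterns evoked by a set of experimental conditions. This
representational dissimilarity matrix (RDM) is symmetric with a zero
diagonal, so `repsim` stores only the upper triangle, row-major, diagonal
excluded — the same pair order as `stats::dist()`. Every function in the
package consumes and emits this canonical vector.

Three pattern dissimilarities are supported: correlation distance (1 minus
the Pearson correlation across channels), Euclidean distance (root sum of
squared channel differences, deliberately *not* normalized by channel
count), and Mahalanobis distance (Euclidean distance after whitening the
channels by an inverse noise covariance; a singular covariance must be
regularized by diagonal loading, exposed as the `regularize` fraction of
the mean diagonal).

A *reference* RDM (typically a brain region, one estimate per subject) is
explained by *candidate* RDMs (models). Because a model is normally taken
to predict only the rank order of dissimilarities, rank correlations are
the default comparators. Kendall's tau-a — concordant minus discordant
pairs over *all* pairs, ties counting in the denominator only — is the
coefficient of choice when candidates predict tied dissimilarities
(categorical models): Spearman and tau-b treat ties generously and can
prefer a degraded categorical model over the true model. tau-a is
implemented twice: an O(n log n) merge-sort algorithm in C++ (production)
and an O(n^2) pair enumeration in R (`kendall_tau_a_ref`, the reference
oracle); the test suite cross-checks them on a thousand random tied and
untied inputs. A caveat found during validation: the "tau-a is more
conservative than Spearman for tied predictions" intuition holds in
*magnitude* (|tau_a| <= |rho| in exhaustive small-n enumeration), not
signed — for negative associations tau-a is the one closer to zero.

## Statistical inference

`select_tests()` encodes the default decision process:

* **12 or more subjects** — subject is a random effect; RDM relatedness is
  tested by a one-sided Wilcoxon signed-rank test across the per-subject
  candidate–reference correlations, and candidate pairs are compared by
  two-sided signed-rank tests on per-subject correlation differences.
* **Fewer than 12 subjects but 20 or more conditions** — fixed-effects
  fallback: relatedness by stimulus-label randomization (the same
  permutation applied to rows and columns of the reference RDMs),
  candidate comparison by bootstrap resampling of the stimulus set.
* Anything can be requested explicitly (`overrides`), with a logged
  notice — except randomization below the 20-condition minimum, which is
  refused because the permutation null is too coarse (at 6 conditions
  there are only 720 distinct permutations).

Numerical choices worth recording:

* Signed-rank p-values use the exact null distribution for n <= 25 when
  the absolute values are untied, and a tie-corrected normal approximation
  otherwise. Zero differences are dropped (Wilcoxon convention); the
  all-zero case returns p = 1.
* Randomization p-values use the (1+k)/(1+N) estimator, so they are never
  0 and never exceed 1. When `factorial(n_conditions)` does not exceed the
  requested permutation count, all permutations are enumerated; the
  identity permutation reproduces the observed statistic and supplies the
  "+1", giving exactly p = 1/n! when only the identity attains the
  maximum.
* Bootstrap samples that collapse to fewer than 3 distinct conditions are
  redrawn (logged). Pairs formed by duplicate draws of the same condition
  are excluded: their dissimilarity is structurally zero and would bias
  rank correlations.
* Multiple testing across the pairwise candidate matrix uses
  Benjamini–Hochberg FDR by default (Bonferroni FWE as the alternative),
  implemented directly as the step-up rule and cross-checked against
  `stats::p.adjust` in the tests.
* Error bars are across-subject standard errors of the mean correlation in
  signed-rank mode and bootstrap standard deviations in bootstrap mode —
  the figure conventions are not uniquely determined, so these choices are
  documented rather than claimed.
* Candidates whose role marks them as measured data (other brain RDMs)
  carry noise; `run_inference()` flags them (`noise_affected`), since
  performance comparisons between candidates affected by noise to
  different degrees should not be formally interpreted.

## The noise ceiling

No model can exceed the correlation supported by inter-subject
variability. The *upper bound* is the mean correlation between the
single-subject RDMs and a "central" RDM overfitted to the group; the
*lower bound* replaces the central RDM by the leave-one-subject-out
average. The central RDM depends on the correlation type: the mean of
z-transformed RDMs (Pearson) or rank-transformed RDMs (Spearman) is the
exact maximizer of the respective average correlation, because after those
transforms squared Euclidean distance is proportional to the correlation
distance. tau-a has no closed-form maximizer; we initialize at the
rank-transform mean and refine by greedy coordinate search over the
subjects' rank values, which is monotone in the objective by construction.
Refinement is capped at `refine_max_pairs` (default 1000) pairs: beyond
that the initialization is used directly and the tau-a upper bound is
documented as approximate. With two subjects the lower bound degenerates
to the between-subject correlation (warned).

## The linear-discriminant t (LD-t)

For each condition pair, a Fisher discriminant `w = Sigma^-1 (p1 - p2)` is
fitted on one data partition (with `Sigma` pooled from that partition's
residuals), the other partition's condition contrast and residuals are
projected onto `w`, and the t value is the projected contrast over its
standard error at the test partition's residual degrees of freedom. The
statistic is a crossvalidated, noise-normalized variant of the Mahalanobis
distance; it can be negative, and under the null it follows a Student t
distribution, so `pt()` converts it to an instant per-pair p-value.
Because the full RDM in the figures is symmetric while the text defines a
single direction, `ldt_rdm()` averages the two crossvalidation directions.
The contrast variance scale is `c'(X'X)^-1 c` when GLM design information
is available and 2 (two independent unit-variance estimates) otherwise;
degrees of freedom are `T - K` on the GLM path and caller-supplied for
directly constructed partitions. The t value is invariant to the norm of
`w`, so no normalization of the discriminant is needed.

## Searchlight mapping

`spherical_neighborhoods()` collects, for every in-mask voxel, the in-mask
voxels within a millimetre radius (anisotropic voxel sizes honored;
spheres clipped at mask borders; centers always included; centers whose
clipped neighborhood falls below `min_voxels`, default 10, are left
undefined). At each center the neighborhood RDM is compared with a model
RDM — correlation distance and Spearman comparison by default, tau-a
optionally (it is markedly slower inside resampling loops). Group
inference applies the *same* signed-rank and BH implementations as the ROI
module, voxelwise, with undefined voxels excluded from the FDR family
rather than assigned p = 1.

## What the simulator emulates — and what it does not

`make_fig4_scenario()` builds a synthetic analogue of a condition-rich
group study: a ground-truth RDM with two main clusters (animate /
inanimate) and a face sub-cluster, mixed from a categorical component and
a continuous item-level geometry; 92 conditions, 100 channels and 12
subjects by default. Ground-truth patterns are produced by
`patterns_from_rdm()`: points initialized from an isotropic Gaussian (or
classical MDS) are driven toward the target geometry by pairwise spring
forces, accepting only stress-reducing steps (the stress trajectory is
non-increasing by construction; step size halves on rejection and re-grows
on acceptance). Non-embeddable targets settle at a positive residual
stress that is reported, never hidden. Subjects observe the ground-truth
patterns plus i.i.d. isotropic Gaussian noise, each from its own seeded
stream.

Two generator parameters required decisions:

* **Mixing weight.** The weight combining the categorical component with
  the continuous geometry is not fixed by any external constraint and is
  exposed as `categorical_weight`. The default is 0.7: the categorical
  divisions dominate the geometry, as they visibly do in the inferotemporal
  cortex RDMs this scenario emulates. At equal weighting the
  characteristic failure mode of Spearman with categorical candidates
  (tied-rank models outranking the true model) is only marginally present,
  i.e. the scenario would not be in the regime it is meant to demonstrate.
* **Noise level.** "Realistic" noise is defined operationally: `noise_sd`
  (default 0.21) was calibrated once so that the mean Spearman correlation
  between a single-subject RDM and the ground truth is approximately 0.5
  at the default geometry, and frozen.

The simulator reproduces the *mechanisms* of real data — categorical
geometry, inter-subject measurement noise, tied model predictions, fMRI
temporal/spatial autocorrelation (`simulate_fmri()`: double-gamma HRF
design, Gaussian-smoothed errors, `Y = XB + E`) — but not the real data's
non-Gaussian noise, inter-subject geometry differences, or physiological
confounds. A green test therefore establishes that the statistical
machinery behaves as specified under its own assumptions, not that those
assumptions hold for any particular dataset.

## Geometry summaries

`mds_2d()` minimizes metric stress by SMACOF majorization from the best of
several seeded starts (classical MDS plus random configurations),
reporting normalized stress `sqrt(sum((d - delta)^2) / sum(delta^2))`.
Any metric-stress minimizer is acceptable for this purpose; majorization
was chosen for its monotone convergence. t-SNE is deliberately excluded:
it is stochastic and offers no acceptance surface. Hierarchical clustering
wraps `stats::hclust` (average, single, complete linkages) and preserves
condition labels.

## File formats and the command line

Single objects travel as CSV (pattern sets: label column + channels; RDMs:
labeled square matrix, or vector + JSON sidecar recording labels, pair
order and measure — both dialects load identically). RDM collections are a
CSV of stacked dissimilarity vectors with a JSON sidecar; volumes are a
single JSON document. These plain-text containers replace binary
HDF5/NIfTI interfaces, which would require packages unavailable in this
package's runtime; the I/O contract (lossless numeric round trip, label
preservation, shape validation with informative errors) is unchanged and
tested. The `rsa` script (installed under `exec/`) dispatches the
subcommands `compute-rdm`, `compare`, `ceiling`, `infer`, `ldt`,
`searchlight`, `simulate`, `mds`, `cluster`; every run writes a
`*.provenance.json` with the arguments, seed and package version, and
reruns with the same configuration are byte-identical.

## Known limitations

* The tau-a noise-ceiling upper bound is approximate (greedy refinement,
  or plain initialization for large RDMs).
* Basic bootstrap tests are slightly optimistic; bias-corrected and
  accelerated variants are out of scope.
* No cluster-extent or permutation-based FWE searchlight inference; no
  surface-based searchlights.
* Partial RDM correlations, tau-c, model-parameter fitting, and
  time-resolved analyses are out of scope.
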