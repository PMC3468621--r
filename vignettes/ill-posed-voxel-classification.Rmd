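---
title: "Linear classifiers, kernel conditioning, and the curse of dimensionality in voxel-based morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear classifiers, kernel conditioning, and the curse of dimensionality in voxel-based morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Classifying subjects from whole-brain gray-matter (GM) density maps is a
linear problem with far more variables than observations: tens of thousands
to hundreds of thousands of voxels against a few hundred subjects. Folklore
says such problems must suffer from the curse of dimensionality and require
aggressive feature selection. This package implements the opposing analysis:
treat the classification task as a *discrete linear ill-posed problem*, where
the operative quantity is not the raw dimension `d` but the conditioning of
the n-by-n linear kernel (Gram) matrix

    K = X X',    K = U S U'  (eigen = singular decomposition, K is PSD),

whose condition number sigma_max / sigma_min measures solution stability.
Three linear classifiers spanning the regularization spectrum are compared
across a sample-size-by-dimension grid:

- **LRC** — the least-squares classifier `a = K^+ y`, `w = X'a` (Moore-Penrose
  pseudo-inverse; minimum-norm least squares). The pseudo-inverse removes
  only *zero* singular values, so small nonzero ones pass through amplified:
  LRC is the canary for poor conditioning.
- **RLR** — logistic regression with the elastic-net penalty
  `lambda * ((1-alpha)/2 ||b||^2 + alpha ||b||_1)`, fitted by cyclic
  coordinate descent on the penalized quadratic approximation. The mixing
  weight defaults to `alpha = 0.001` (nearly ridge, residual L1 sparsity),
  with `lambda` tuned by cross-validation.
- **SVM** — soft-margin linear SVM solved in the dual on the precomputed
  kernel. In the spectral view the penalty is a *generalized ridge*: solution
  components along low-eigenvalue eigenvectors are shrunk hardest. The
  hard-margin machine is the `C = 1e6` limit of the same problem.

Evaluation follows a fixed-test-set design: a balanced held-out test set is
drawn once per study seed; training sets of increasing size are drawn from
the remainder; `lambda` and `C` are selected by stratified 10-fold CV grid
search maximizing mean fold accuracy (ties toward stronger regularization);
accuracy is `(TP + TN) / total` with the disease class positive. The LRC has
no hyperparameter and is fitted on the full training set directly.

## The synthetic cohort

The original data are access-restricted, so experiments run on a seeded
synthetic GM cohort built to the same statistical skeleton:

- a **probability template**: a smooth random field monotonically requantiled
  so that thresholds 0.86 / 0.65 / 0.2 / 0.0021 carve out four nested masks
  with prescribed sizes (defaults proportional to the reference study's
  50K : 150K : 310K : 750K voxel dimensions). Monotone requantiling makes
  nesting exact and mask sizes accurate to ties (none, for a continuous
  field);
- two classes (CN / AD) differing by a spatially localized GM reduction over
  an `effect_region` inside the highest-threshold mask, so the informative
  voxels survive every analysis dimension;
- additive Gaussian noise smoothed with an isotropic kernel (FFT, periodic
  boundary) and rescaled to a stated marginal standard deviation, creating
  the correlated-voxel structure of smoothed morphometry data;
- densities clipped at zero.

**Physical scale.** All lengths are stated in millimetres and converted by
the grid scale: the default 32^3 grid spans a 150 mm field of view (voxel
~4.7 mm), the 4 mm smoothing kernel is therefore ~0.85 voxels, and the
default atrophy region is a 9.4 mm-radius sphere (~hippocampal volume,
~33 voxels) at effect size 1 noise-SD per voxel. Scaling lengths *together*
is what keeps the desk-scale study in the same statistical regime as the
full-resolution problem — many more effective voxel degrees of freedom than
subjects at every mask, hence full-rank, moderately conditioned kernels. An
early version fixed the smoothing kernel in voxels while shrinking the grid;
that quietly moved the world into an `n > d_eff` regime where every kernel
is near-singular and the least-squares classifier is at chance everywhere —
a regime the reference findings never occupied.

What a green pattern test does establish: the orderings (accuracy vs n,
conditioning vs n and d, regularized-vs-unregularized gaps) under the stated
generative world. What it does not: real-data effect sizes, anatomical
covariance (real anatomy has high-rank inter-subject variability and
long-range correlations this generator does not model), scanner or site
effects, or the absolute accuracy levels of any clinical dataset.

## Design decisions that were genuinely open

**Standardization scope.** Features are standardized voxel-wise
(mean 0, SD 1). Fitting those parameters on the training set only is the
leakage-safe choice and is the default of the low-level API
(`fit_standardizer`). The experiment drivers default to *pooled* (whole
sample) standardization instead, for a structural reason: train-only
standardization forces every training column mean to zero, making rows sum
to zero and `K` exactly rank n-1 in every cell — while the reference
analysis reports full-rank kernels throughout, which identifies its
"always normalized" preprocessing as a single whole-sample pass. Both modes
are exposed (`standardize = "pooled" | "train"`).

**LRC intercept.** The textbook dual form `a = K^+ y` has no intercept. For
balanced 0/1 labels and standardized features that is *not* benign: the
label mean (0.5) cannot transfer to held-out subjects through a minimum-norm
interpolator — held-out decision values center at or below zero, and the
0.5-threshold rule degenerates to the majority class no matter how strong
the signal. `fit_lrc` therefore defaults to an intercept via standard kernel
centering, `a = (HKH)^+ (y - ybar)`, `f(x) = ybar + (k_x - K1/n)'a`, which
also makes the all-components PC-space LRC *exactly* equal to the
voxel-space LRC (PCA scores are train-centered). `intercept = FALSE`
recovers the literal pseudo-inverse solution used by the dual-primal
equivalence checks.

**Hyperparameter grids.** The reference grids are typographically lost; the
package defaults span null-model to near-unregularized regimes
(25 log-spaced lambdas in 10^[-4, 1]; 21 powers of two in 2^[-10, 10]).
Note the meaningful range of `C` scales inversely with kernel magnitude
(kernel entries grow with d for standardized voxels), so CV on these data
selects small `C`; pattern tests use compact grids covering that range.

**Component selection in PC space.** Incremental selection refits each
classifier on the first m components, m = 1..M, and takes the *maximum test
accuracy* over m — the reference protocol, reproduced as described. This
maximum is optimistic by construction (it selects on the evaluation data);
a cross-validated selector is provided (`selector = "cv"`) as the
non-default alternative. At desk accuracy levels (~0.6-0.7) the optimism is
visible at about +0.03 to +0.05, which should be kept in mind when reading
the parity results.

## Numerical choices

- Pseudo-inverse / numerical-rank cutoff: eigen- or singular values below
  `n * eps * sigma_max` count as zero (standard convention; the source
  delegates this to its numerical environment).
- RLR solvers: glmnet for large voxel matrices; an in-package C++ cyclic
  coordinate-descent solver (identical objective, warm-started paths) for
  the many small dense problems of per-component CV. Both are verified
  against each other and against a generic BFGS minimizer of the penalized
  deviance; KKT (subgradient) residuals certify stationarity to 1e-6 or
  better on fitted models.
- SVM solver: maximal-violating-pair SMO with second-order pair ranking,
  exact 1-D feasible-interval clipping, bound snapping (floating dust at the
  box otherwise stalls progress), optional warm starts across the C grid and
  across incremental kernel growth (with O(n) gradient correction per
  rank-one kernel update). Stopping rule `m(alpha) - M(alpha) <= eps`,
  default 1e-6; inner CV loops use looser eps since only the fold-accuracy
  ranking matters there.
- Ties: decision value exactly at threshold goes to the positive (disease)
  class; CV ties go to the more regularized hyperparameter; template
  requantiling breaks rank ties by first occurrence.
- Degenerate inputs: empty masks error with the offending threshold;
  zero-SD voxels standardize to zero rather than being dropped; all-zero
  kernels report rank 0 with a warning; non-convergence of RLR errors with
  the last objective.
- Seeds: one master seed; every (purpose, cell, iteration) coordinate maps
  to a child seed through an overflow-safe Lehmer mixer, so any execution
  order (or parallel schedule) reproduces identical results.

## Known limitations

- The parity test between voxel and PC space inherits the reference
  protocol's test-set maximum; at desk accuracy levels the acceptance suite
  finds the unregularized LRC's PC-space gain slightly exceeding the 0.05
  parity band (its direction — LRC and SVM gaining, RLR losing — matches
  the reference finding). The band is asserted as stated and the result is
  reported as the suite computes it.
- The generator's one-region, fixed-amplitude effect understates the
  widespread, heterogeneous atrophy of real disease; consequently accuracy
  *decreases* with dimension here (signal fraction dilutes), whereas the
  reference data often showed the opposite. Per-dimension patterns (accuracy
  vs n; conditioning orderings) are unaffected.
- Periodic-boundary smoothing is statistically convenient (homogeneous
  variance) but not anatomically meaningful near the field-of-view edge.
- The hard-margin SVM on non-separable data is solved as the C = 1e6 box
  problem; at that C the KKT gap tolerance is interpreted on the same
  absolute scale, so "hard-margin" fits on inseparable data are approximate
  minimizers (as they are in any practical solver).
- NIfTI support is deliberately minimal (single-file NIfTI-1, 3-D volumes,
  common datatypes, pixdim only); it exists because no NIfTI package is
  available in the target environment.
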