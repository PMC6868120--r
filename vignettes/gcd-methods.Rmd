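---
title: "Granger causality density mapping: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger causality density mapping: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gcdmap)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic benchmarks do and do
not demonstrate.

## The causality model

For an ordered voxel pair (x → y), `fit_bivariate_var()` fits by ordinary
least squares a restricted autoregression of the target on its own `order`
lags (plus intercept) and a full model that adds the predictor's lags over
the same range. The influence value is the log ratio of residual
magnitudes, `f = ln(|e1|/|e2|)`, and significance comes from the
nested-model F statistic with `(order, n_obs - 2*order - 1)` degrees of
freedom, where `n_obs = T - order`. Both quantities are monotone transforms
of the classical likelihood-ratio Granger statistic; the F-test is used
because the density definition is a hard threshold (p < 0.05, uncorrected)
and the nested F-test is the canonical finite-sample test for OLS-nested
models.

Two readings of `|e|` exist in the field: residual standard deviation and
residual variance. They differ exactly by a factor of 2 in the log and
therefore scale every density map by 2 without changing any rank, test or
classification result. The package defaults to the standard-deviation
reading (`f = 0.5 * ln(RSS1/RSS2)`) and exposes
`residual_measure = "var"`.

The lag structure is the full range `1..order` with `order = 1` by default.
A data-driven per-pair lag window is deliberately not attempted: with
~200-20,000 voxels the pairwise search is combinatorially unstable, and a
fixed order keeps the estimator aligned with the VAR(1) generator used for
validation. Users can raise `order`; the higher-order path is a per-pair
OLS loop validated against the same brute-force oracle as the fast path.

`compute_gcd_maps()` applies the significance threshold symmetrically to
both directions (the inflow sum is thresholded exactly like the outflow
sum), uses one pair of fits per unordered pair, and flags near-constant
voxels as degenerate: they contribute zero to every sum rather than NaN.
The order-1 path is closed-form linear algebra over centered lag
cross-products (O(V^2) memory, a few seconds for V = 200), numerically
identical (to 1e-10 in tests) to the per-pair loop.

### Map algebra

`total_flow = inflow + outflow` and `int_flow = inflow - outflow` are
derived fields, so these identities hold exactly by construction. A voxel
with strongly negative int-flow is a net sender (causal source); strongly
positive, a net receiver.

## Preprocessing chain

Order is fixed and logged: volume discard (default 10) → FD computation and
scrubbing → nuisance regression → linear detrend → band-pass (0.01–0.1 Hz).
Choices worth stating:

* **FD** is the Power-style sum of absolute backward differences of the six
  rigid-body parameters, rotations converted to arc length at a 50 mm head
  radius. The motion *regression* model is the Friston-24 expansion (6
  parameters, their one-frame lags, both sets squared). These are distinct
  roles: a 24-parameter expansion defines no displacement scalar.
* **Scrubbing** replaces frames with FD > 0.5 mm by per-voxel linear
  interpolation between the nearest kept frames (edge frames copy the
  nearest kept value) and keeps them in the series: the autoregressions
  need contiguous time, so deletion is not an option. Interpolated frames
  are recorded in `censored_frames`.
* **Nuisance regressors** are the Friston-24 expansion plus the mask-wide
  mean ("global signal"); on synthetic grids there is no tissue
  segmentation, so white-matter/CSF averages enter only through
  `extra_regressors` when masks exist. Whether global-signal regression
  should precede or follow scrubbing is not settled practice; the package
  fixes scrub-then-regress and documents rather than defends it.
* **Band-pass** is a 4th-order Butterworth applied forward-backward
  (zero phase — phase shifts would bias lagged causality estimates), after
  demeaning and odd-reflection padding of 30 samples per end; without the
  padding, zero initial filter states leave edge transients larger than the
  passband signal itself. The passband default 0.01–0.1 Hz is the
  conventional slow-fluctuation band; at TR = 2 s the Nyquist frequency is
  0.25 Hz.

## Classification

**Per-voxel maps** (`voxelwise_accuracy_map()`): one linear SVM (C = 1) per
voxel on that voxel's single value, leave-one-out cross-validated. No
searchlight: the map is meant to localize, and a radius would smear it.
Clusters are 6-connected components (18/26 available) of voxels above 70%
accuracy with at least 5 members. "More than 5 voxels" in common usage is
ambiguous between > 5 and >= 5; the package reads it as >= 5 and exposes
`min_extent`.

**Combination classifier** (`nested_cv_classify()`): features are the
concatenated voxel patterns of the chosen density metrics. The outer loop
is stratified 5-fold CV repeated 5 times; within each outer training set a
stratified 4-fold inner loop runs the SVM-RFE elimination sweep (drop the
10% of features with smallest squared weights per step) and reads the
accuracy-vs-feature-count curve off the held-out inner-fold predictions of
the very models trained during the sweep — the same estimator, no extra
fits. The selected count (ties resolved toward fewer features) is refitted
on the whole outer training set. Four folds keep both classes in every
inner fold at 21 + 21 subjects after the outer split. Standardization, the
sweep and the selection see training subjects only; the leak test in the
suite injects a feature discriminative only on a held-out fold and checks
that the inner accuracy does not move.

Accuracy, sensitivity and specificity are computed from the pooled
held-out records at the SVM's zero-decision threshold (so the identity
`acc = (sens*n_pos + spec*n_neg)/n` holds exactly); the AUC is the
trapezoidal-rule area over the pooled decision values. Whether published
sensitivities of this kind are quoted at the zero threshold or an
ROC-optimal one is often unstated; the zero threshold is the only one that
needs no extra data. The positive class (the one sensitivity refers to)
defaults to the second factor level — `substate_B`, the effect-carrying
group in the simulator — and is exposed as `positive`.

The **permutation test** relabels subjects completely at random `n_perm`
times (default 100) and re-runs the nested CV per relabelling with one
outer repetition; `p = (1 + #{perm >= obs}) / (n_perm + 1)`. The observed
statistic keeps its 5 repetitions: averaging repetitions shrinks variance
but not the mean, so comparing a 5-repeat observed value against 1-repeat
permutations is slightly conservative under the null and was chosen for
runtime.

**PCA** (`pca_reduce()`) and **ReliefF** (`relief_select()`, k = 5 nearest
hits/misses on standardized features, all subjects probed once,
deterministic index tie-breaks) serve the two companion pipelines —
single-metric dimension reduction and reduced-feature-set sweeps
(50–5,000 features) — and are kept out of the default combination path.

### The SVM solver

All SVM fits go through an exact sequential-minimal-optimization solver for
the linear C-SVC dual, written in C++ over a precomputed Gram matrix. The
RFE sweep retrains a model at every elimination step, and nested CV plus
permutation testing multiply that into ~10^5 small fits per cohort; the
Gram-matrix formulation lets each elimination step *downdate* the kernel in
place instead of recomputing it. The solver is validated against libsvm
(e1071) in the test suite: on random problems the primal objective is at
least as low as libsvm's at its own tolerance and the weight vectors agree
to ~1e-3.

## The synthetic cohort generator

`network_spec()` defines a stationary VAR(1) over the in-mask voxels of a
grid: `x_t = self * x_{t-1} + A' x_{t-1} + drift + noise`, with per-voxel
sinusoidal drift (one cycle per run, below the passband) and Gaussian
innovations. Defaults — 8x8x8 grid with a spherical mask of ~200 voxels,
T = 240 retained volumes at TR = 2 s, self-coupling 0.3, unit noise — mirror
a desk-scale version of a typical pediatric resting-state acquisition
(250 volumes minus 10 discarded). `simulate_cohort()` plants a group
difference by adding `delta` (default 0.5) to 10 hub-to-neighbor coupling
edges in group `substate_B`, jitters every subject's nonzero couplings
(sd 0.02), draws demographics (age ~ N(8.7, 2), sex ~ Bernoulli(0.5),
duration ~ |N(20, 18)|), and synthesizes motion traces whose occasional
spikes cross the 0.5 mm FD threshold so the scrubbing path is always
exercised. All randomness derives from one integer seed; subject i uses
seed + i.

What the generator does *not* emulate: hemodynamic convolution (an optional
exponential smoothing would blur lags; the default keeps generator and
estimator orders aligned so that recovery failures indicate bugs, not model
mismatch), spatial autocorrelation of noise, physiological rhythms, and
tissue structure. Passing benchmarks on this generator therefore shows the
estimator and classifier are correct *for the model they assume*, not that
real hemodynamics cannot distort voxelwise causality — a known and debated
limitation of lag-based methods on BOLD data.

## Benchmark sizes and numerical choices

The test suite and `scripts/acceptance.R` run, as the package's chosen
problem sizes: type-I-error calibration over 2,000 null pairs at T = 200
(expected rejection 0.05 ± 0.02); hub recovery over 50 seeds on ~20-voxel
grids (coupling 0.5, T = 200, top-1 outflow rank in >= 95% of seeds);
one strong-effect cohort (21+21, delta 0.5 on 10 edges, 240 retained
volumes, ~200 voxels) expected to reach AUC >= 0.9 and accuracy >= 85%; and
20 null-cohort seeds with 49 permutations each (p granularity 0.02),
expected to stay at chance accuracy with p > 0.05 in >= 90% of seeds.

Numerical conventions: voxel grid coordinates are 1-based array indices
(the R convention; world coordinates only via the affine); a missing TR in
a 4D header is a hard error, never a silent default, because filter design
and lag semantics depend on it; motion files default to radians with a
degrees flag; SMO convergence tolerance is 1e-6 on the KKT gap with
box-snapping at 1e-12 to avoid stalls; degenerate voxels (variance below
1e-12 relative) are excluded from density sums and flagged; RFE ties break
by feature index so that runs are bit-reproducible.

## Known limitations

Pairwise bivariate causality cannot distinguish direct from mediated
influence (a conditional, community-aggregated variant would; it is not
implemented because its specification is not settled). The density sums use
uncorrected p < 0.05 by design, so single-pair significance claims should
not be read off the maps. Whole-brain use is O(V^2 T): the CLI refuses more
than 20,000 in-mask voxels without `--force` and offers `--downsample`.
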