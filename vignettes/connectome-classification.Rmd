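---
title: "Classifying functional connectomes with multi-width row convolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying functional connectomes with multi-width row convolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conncnn)
```

## The problem

Resting-state fMRI summarizes each subject as an R x R *functional
connectome*: the matrix of Pearson correlations between the mean BOLD time
series of R brain parcels (ROIs). Psychiatric conditions such as autism
spectrum disorder (ASD) are associated with distributed disruptions of this
connectivity pattern, and a long line of work tries to classify patients
versus typical controls (TC) directly from the connectome. `conncnn`
implements one such classifier — a convolutional network whose filters are
matched to the row structure of the connectivity matrix — together with the
evaluation protocol (stratified 10-fold and leave-site-out cross-validation),
a gradient-based saliency method for ranking discriminative ROIs, classical
SVM/KNN/RF baselines, and a synthetic-cohort generator that makes the whole
pipeline testable without any imaging data.

## The model

The input is the full R x R correlation matrix (diagonal of ones included).
Row i of the matrix is the connectivity profile of ROI i, so a filter that
spans an entire row scores one region's relationship to the whole brain.
The network runs several such branches in parallel:

* branch k (k = 1, ..., 7 by default) convolves `n_filters` filters of shape
  k x R along the row axis only (valid convolution, stride 1), so each of
  the R − k + 1 positions jointly scores k *adjacent* ROI profiles;
* each branch applies `tanh` and then a **global max over positions**,
  yielding one feature per filter;
* branch outputs are concatenated (|K| · F features), passed through dropout
  (only `keep_prob` of the features are kept during training), and a single
  dense softmax layer produces the two class probabilities.

With R = 392, K = 1..7 and F = 400 filters per branch, the parameter count
is

```
F·R·(1+2+...+7) + 7·F     convolution weights + biases   = 4,393,200
7·F·2 + 2                 dense weights + biases          =     5,602
                                                   total  = 4,398,802
```

`count_parameters()` returns this closed form and the test suite asserts
that `build_model()` allocates exactly that many scalars. The arithmetic is
also why the pooling must be *global*: 4,398,802 = 400·392·28 + 2,800 +
2,800·2 + 2 leaves room for exactly one dense layer acting on a 2,800-long
feature vector, which forces one max per (branch, filter) and no
intermediate hidden layer. Any local pooling would multiply the dense fan-in
by the number of surviving positions and overshoot the count by orders of
magnitude.

Two further architectural readings were open and are resolved as follows.
`tanh` is applied before pooling; since `tanh` is monotone and pooling is a
max, applying it after pooling is mathematically identical, so nothing hinges
on the order. Dropout keeps 25% of the features (`keep_prob = 0.25`), read
literally from the description of the reference model; if the authors meant
a drop-*rate* of 25% the behaviour is recovered with `keep_prob = 0.75`,
which is why the value is exposed as a parameter.

### Training

Categorical cross-entropy, minibatches of 32, learning rate 0.005, 300
epochs by default (the reference description gives 300 in one place and 400
in another; both are reachable via `train_config()`). The optimizer is not
specified in the reference description; the package defaults to Adam
(adaptive moments), with plain SGD behind a flag. Weights use Glorot-uniform
initialization. Training is deterministic given `train_config(seed = )`:
initialization, shuffling and dropout masks all derive from it, and the
caller's RNG state is untouched. There is no deep-learning framework
dependency: forward, backward and the optimizer are implemented directly on
BLAS matrix products, which is fast enough because the convolution reduces
to one patch-matrix multiplication per branch.

Note on memory: training caches stacked patch matrices when they fit in
roughly 1 GB and otherwise rebuilds them per minibatch, so large-R
configurations trade speed for memory automatically.

## Evaluation protocol

`stratified_kfold()` deals subjects within each class round-robin after a
seeded shuffle, so per-fold class proportions are within one subject of the
cohort proportions. `leave_site_out()` makes one fold per acquisition site
(test = that site, train = the rest), ordered lexicographically.
`cross_validate()` re-initializes and re-trains the model per fold with a
per-fold seed derived from the master seed.

Per fold, `compute_metrics()` reports accuracy, a 95% Wald half-width
(`1.96·sqrt(p(1−p)/n)`), sensitivity (ASD recall), specificity (TC recall),
the ASD F-score, the rank-based (Mann–Whitney) AUC — identical to the
trapezoidal ROC area, ties by midrank — and the 2x2 confusion matrix. If a
fold lacks one class, the undefined metrics are `NA`, never 0.

Two aggregation conventions exist in the literature and the package reports
both: the **unweighted** arithmetic mean across folds (the default `Mean`
row — this is the convention consistent with published ten-fold F-score
columns, whose per-fold values average exactly to the printed mean) and a
size-weighted mean (`weighted_mean_row`), because fold sizes are unequal
under leave-site-out and published mean accuracies sometimes reflect
weighting. The Wald form of the confidence interval is itself an inference:
it reproduces the printed interval for several published leave-site-out rows
(e.g. half-width 0.07 at accuracy 0.65, n = 175) though not all of them at
two-decimal rounding. The ROC is computed on out-of-fold predictions pooled
across folds.

## Saliency

`input_gradient()` returns the exact analytic gradient of the **pre-softmax
class score** with respect to every input entry, with dropout disabled.
Pre-softmax is the standard choice for class saliency: the softmax couples
the classes and saturates, while the raw score gradient is linear in the
upstream weights (a property the tests exploit). The gradient flows only
through each filter's argmax position, so per-subject maps are sparse in
rows.

`roi_scores()` turns a map into per-ROI importance; the default aggregation
credits ROI i with the total absolute gradient over its row and column
(counting the diagonal once). Cohort-level maps (`cohort_saliency()`)
average absolute per-subject maps over the correctly classified ASD
subjects — the cohort whose shared discriminative pattern the ranking is
meant to expose; pooling over all subjects is available. Ranking ties break
by ascending ROI index for reproducibility.

## Baselines

Features for SVM/KNN/RF are the strictly-upper-triangle correlations
(length R(R−1)/2; the diagonal carries no information). Features are
z-scored with training-fold statistics for the SVM (kernels need scale);
KNN and RF see raw correlation units. Fixed "before optimization" settings:
SVM RBF with C = 8, KNN with k = 20, RF with 100 trees and a node cap of
300. Grids "after optimization": SVM kernels {linear, rbf, poly, sigmoid}
crossed with C ∈ {0.5, 1, 2, 4, 8, 16} (the C grid is a package choice —
the reference protocol names only the kernels); KNN k ∈ {4, 8, ..., 40};
RF node cap 120..600 step 60 crossed with tree count 20..180 step 20.

The RF depth-like axis deserves a note: the reference wording conflates the
maximum number of features, tree depth and levels per tree. The package
exposes the two tuned axes that match the printed ranges — a terminal-node
cap (`maxnodes`, the depth-like axis) and the number of trees — and a cap
larger than a small training fold supports is silently truncated by the
forest, which is the intended behaviour.

SVM scores are squashed signed margins (`plogis` of the decision value)
rather than Platt-calibrated probabilities: on small folds Platt's internal
cross-validation is noisy and can even disagree with the margin sign, while
the margin keeps argmax decisions and AUC exact and deterministic.

Grid selection maximizes the unweighted mean CV accuracy; ties go to the
first point in `expand.grid()` order (first axis fastest), which is fixed
and documented.

## The synthetic generator

`simulate_connectomes()` draws each off-diagonal edge in Fisher-z space,
`z_ij ~ N(base_mu + site_offset + planted·delta, noise_sd²)`, and maps it
through `tanh`, which guarantees entries in (−1, 1) and gives the
closed-form expected group difference `tanh(base_mu + delta) −
tanh(base_mu)` on planted edges. `planted` is 1 only for ASD subjects on
edges joining two planted ROIs, so the group difference is a localized
block — the structure the saliency ranking is supposed to find. Site
offsets (one per site, `N(0, site_sd²)`) shift all of a site's edges,
emulating scanner/protocol differences; subjects are assigned to sites
round-robin. `mean_fd` is Uniform(0, 0.3) so the motion filter path is
exercisable. `simulate_timeseries()` instead plants a latent shared signal
(loading 0.3 for TC, +0.6 for ASD on planted ROIs, unit noise elsewhere), so
`pearson_connectome()` is tested end to end; the induced planted-edge
correlation is approximately c²/(c²+1) at loading c.

Defaults — 100 subjects per group, 64 ROIs, 8 planted ROIs, delta 1.0,
base_mu 0.2, noise_sd 0.3, 4 sites with site_sd 0.1 — are the study
conditions used by the test suite, sized so that a scaled network (branches
1–3, 32 filters, 30 epochs) finishes a 10-fold CV in under a minute on one
CPU. What the generator does **not** emulate: hemodynamic autocorrelation,
motion artefacts, global signal structure, heavy-tailed noise, or realistic
inter-regional covariance beyond the planted block. Passing the planted-
effect tests therefore demonstrates that the pipeline recovers a separable
group difference and localizes it — not that any particular accuracy is
attainable on real cohorts.

## Numerical and protocol choices

* Motion filter: subjects are removed when mean framewise displacement is
  *strictly over* the threshold (default 0.2 mm); a subject exactly at the
  boundary is kept.
* Diagnosis coding: `1 = ASD`, `2 = TC` by default (the public multi-site
  convention), overridable via `dx_map`.
* Correlations: raw Pearson, no Fisher z-transform, diagonal stored as
  exactly 1; the matrix is symmetrized to remove last-bit asymmetry. The
  CNN sees the full matrix including the diagonal; baselines see only the
  strict upper triangle.
* R is taken from the data (default 392 — the usable ROI count of the
  CC400 parcellation, despite the atlas name suggesting 400).
* Zero-variance ROIs are an error by default; `impute_zero = TRUE` sets
  their correlations to 0 with a warning.
* Ten-fold stratification is by diagnosis only, not site.
* Report serialization uses 17 significant digits, so write/read
  round-trips are bit-identical.

## Known limitations

* Training at the full 392-ROI scale is CPU-feasible but slow (the
  reference setup used a GPU); the package is tuned for the scaled
  configurations above.
* No class weighting or imbalance handling; cohorts are assumed roughly
  balanced.
* Saliency significance is not assessed; rankings are descriptive.
* Mapping ROI indices to anatomical labels/MNI coordinates is consumed as
  an optional lookup, never computed.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_connectomes(sim_config(seed = 1))
plan <- stratified_kfold(sim$cohort$diagnosis, k = 10, seed = 1)
mc <- model_config(n_rois = 64, branch_lengths = 1:3, n_filters = 32)
report <- cross_validate(sim$cohort, sim$connectomes, plan, mc,
                         train_config(epochs = 30, seed = 1))
glance(report)
autoplot(report, type = "roc")
```
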