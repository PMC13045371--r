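---
title: "Graph convolution with trainable sparse pooling for multi-site connectome classification"
author: "gcnsp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gcnsp methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Case/control classification from resting-state functional connectivity must
cope with two structural difficulties: each subject is a *graph* (regions of
interest connected by correlated activity), not a feature vector; and
cohorts large enough to train a classifier are pooled across acquisition
sites whose scanners and protocols shift the data distribution. `gcnsp`
implements a graph-convolutional classifier with a trainable sparse-pooling
readout (GCNSP) designed for exactly this setting, together with the
evaluation protocols that make multi-site claims checkable: pooled
cross-validation, leave-site-out testing, and leave-site-out transfer
learning with fine-tuning on a small target site.

## From time series to a population graph

Connectivity is the Fisher transform `z = atanh(r)` of pairwise Pearson
correlations between ROI time series. Two numerical conventions apply: the
self-correlation diagonal is fixed at 0 (atanh(1) diverges and carries no
information), and off-diagonal `|r|` is clipped to 0.999999 so features
stay bounded; both are enforced by `fisherConnectivity()`.

Site effects are removed by **site regression**
(`regressOutSite()`): per edge, an OLS fit of z on one-hot site indicators,
estimated **on the training subjects only**, whose fitted effects (site
mean minus grand mean over the fit set) are subtracted from all subjects.
Fitting on training folds only is a deliberate leakage guard; the source
material does not state the fit population. In leave-site-out evaluation
the held-out site's effect is not estimable without touching its data, so
the held-out site passes through unadjusted — this is part of what makes
leave-site-out hard, and what transfer learning compensates for.

All subjects share one **population graph**: nodes are ROIs, and each node
is connected to its `k = 10` nearest neighbours under correlation distance
`1 - cor` between node connectivity profiles (rows of the *training-fold
mean* connectivity, with the two diagonal-touching entries masked). Two
open choices were closed as follows: neighbourhoods are union-symmetrized
(an edge survives if either endpoint selects it) with binary weights by
default, because the convolution only needs adjacency support; and distance
ties break toward the lower node index for determinism. The propagation
operator is the renormalized adjacency
\(\hat A = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}\), whose spectrum lies in
[-1, 1] (`normalizeAdjacency()`).

Node features are the subject's own connectivity profiles: `X = Z`, an
N-by-N matrix, so the first convolution layer sees each node's full edge
pattern.

## The model

Two convolution layers with ReLU,

\[ Z = \mathrm{ReLU}\big(\hat A\, \mathrm{ReLU}(\hat A X W^{(0)})\, W^{(1)}\big), \]

followed by a **trainable sparse pooling** chain
\(Z_G^i = \Theta^i_{sp} Z_G^{i-1}\) (with \(Z_G^0 = Z\)): a pure linear
coarsening whose matrices are initialised dense and driven toward sparsity
by an L1 penalty \(\lambda \sum_i \|\Theta^i_{sp}\|_1\) — sparsity is
*learned*, not imposed. The flattened pooled layers are concatenated, in
layer order and row-major within a layer, into the graph embedding, which a
**bias-free** linear head maps to two class logits and a softmax. The loss
is standard cross-entropy plus the L1 term plus an L2 penalty on the
convolution and head weights (not on \(\Theta\), which carries the L1 term
instead). Two printed formulas in the source material are nonstandard (the
cross-entropy swaps prediction and truth; the softmax normalization is
written unconventionally); both are implemented in their standard forms.

Design choices where the architecture description was open:

* two pooling layers with ratio 0.5 each (`n_i = ceil(0.5 n_{i-1})`);
* both hidden widths equal one `hiddenSize` (64 default, 16 for
  interpretability runs);
* dropout (0.5) after convolution 1 and on the embedding before the head;
* a single linear output map rather than a stack of dense layers;
* first-order adaptive-moment optimization (Adam) at the stock learning
  rate 1e-4, minibatches of 32 (16 for single-site fine-tuning);
* the head has no bias so that the class-activation conservation identity
  below is exact;
* initialisation is symmetric uniform scaled by fan-in/fan-out.

The forward/backward pass is hand-derived and implemented in compiled code
(`src/gcnsp_core.cpp`); the R-level `gcnspForward()` is the readable
reference path, and the test suite asserts the two agree to machine
precision, alongside a finite-difference check of every gradient block.
All shuffling and dropout draw from R's RNG under a derived seed, so
training is bit-reproducible. The plain-GCN ablation is the same model
with a fixed node-mean readout in place of the trainable pooling.

## Evaluation protocols

* **Multi-site pooling CV** (`multiSitePoolingCV()`): stratified 10-fold
  CV over the pooled sites. Within each fold, site regression, the mean
  connectivity, the K-NN graph and the model are fitted on the training
  fold only; metrics pool the out-of-fold scores. Stratification is by
  label within site, dealing each label class round-robin across folds.
* **Leave-site-out test** (`leaveSiteOutTest()`): train on all other
  sites, score the held-out site, which nothing was fitted on.
* **Transfer learning** (`pretrainGcnsp()` + `transferCV()`): pre-train on
  the source sites, then 10-fold CV within the target site — fine-tune all
  parameters on 90% (batch 16), test on 10%. A stratified 1/9 of the
  training portion is carved out as a validation set, because the 10% test
  fold must stay untouched and the source material does not define one;
  "optimal epoch" re-evaluates the snapshot from the epoch with the best
  validation accuracy (ties to the earliest). Fine-tuning reuses the
  pretrained model's population graph, since the weights are tied to that
  graph's structure; the non-transfer arm (fresh initialisation, same
  protocol) builds its graph from the target training data. Per-site
  metrics average over folds; CV metrics pool out-of-fold predictions.
* **RFE baselines** (`baselineClassify()`): features are the vectorized
  upper triangle; recursive feature elimination ranks by two-sample
  |t| and drops the lowest 10% of survivors per round (step size is our
  choice; the endpoint `max(1, ceil(ratio * d))` with ratio 1e-4 matches
  the stock configuration at ~1.5M-edge dimensionality — on small
  synthetic problems a proportionally larger ratio is the faithful scaled
  analog). Classifiers: linear-kernel SVM at unit cost, LDA, logistic
  regression; features standardized by training-fold statistics.
  Accuracy thresholds probabilities at 0.5; ROC/AUC are computed by an
  exact threshold sweep with trapezoidal integration, cross-checked in
  tests against pairwise concordance and pROC.

Every fitted object records the subject ids that influenced it, and the
protocol results expose per-fold provenance so leakage is testable, not
assumed.

## Interpretability

With a bias-free head the pre-softmax class score decomposes exactly over
the embedding, \(S_c = \sum_x w^c_x z_g[x]\): `camEmbedding()` returns the
per-coordinate contributions, whose sum reproduces \(S_c\) to 1e-8 on every
evaluated subject (a tested invariant). Because the source material does
not specify how node-level activations become edge-level "discriminative
connectivity", two realizations are provided: `camNodes()` backprojects the
embedding scores through the transposed pooling chain to nodes, and
`camEdges()` attributes the class score to individual connectivity entries
by gradient-times-input, symmetrized with zero diagonal — exact for a
network operating in its linear regime. The default (`camEdges`) is the
edge-level tool; `topEdges()` keeps the top 1% by convention.

One property of this default deserves emphasis: gradient-times-input
attributes with respect to the *input features*. If the population graph
is shuffled but the features still carry the group signal, an accurate
model remains accurate and the attribution still localizes the signal.
Graph-shuffle controls (`shuffleAdjacency()`, in adjacency-permuting and
node-order modes) therefore probe the *model's dependence on graph
structure* — on our synthetic data the classifier survives shuffling and
the edge CAM remains precise, which is informative about where the signal
lives (the features), not a defect of the attribution. The expectation
that shuffled-graph training drops CAM precision of planted edges to
chance does not hold for this architecture; the corresponding test in the
suite documents this by failing, by analysis rather than accident.

Feature maps (`extractFeatureMaps()`) are layer outputs averaged over
subjects; `networkOverlap()` associates each channel with the functional
network holding the largest (size-corrected) share of its top 10% nodes
(the threshold is our choice). Group differences use elementwise
pooled-variance t statistics with a Gaussian KDE summary under Scott's
bandwidth rule, floored at 1e-6 for degenerate input.

## The synthetic generator

`generateDataset()` emulates the statistical structure the method assumes,
in z-space throughout: a block-structured baseline (within-network
correlation 0.3, between 0.05), a planted set of group-discriminative
edges shifted by `effectDelta` in patients, i.i.d. symmetric subject noise,
and per-site effects drawn once per site — an additive shift and a
multiplicative scale, the simplest model of a distribution-level site
difference; richer site models are out of scope. A timeseries mode maps
each subject's z-matrix back to a correlation matrix (eigenvalue-clipped to
the nearest positive-definite matrix at 1e-6), draws multivariate-normal
timepoints, and recomputes connectivity, so the full pipeline from T-by-N
data is exercised.

What it does **not** emulate: hemodynamics, motion artifacts, missing data,
heavy-tailed noise, site-by-diagnosis interactions, or realistic network
topography. Passing tests on this generator show the machinery is correct
and calibrated under its stated assumptions — not that comparable accuracy
would be reached on clinical data.

Preset study conditions (fixed once, at design time):

* `separable` — 60 ROIs / 6 networks, 2 sites with 50 patients + 50
  controls each, planted within-DMN block, effect 0.3, noise 0.2, mild
  site effects (shift sd 0.1, log-scale sd 0.05);
* `transfer_benefit` — 40 ROIs, 4 source sites of 40+40 and one target
  site of 20+20, weak effect 0.15 and strong site effects (shift sd 0.25,
  log-scale sd 0.1): single-site training is data-starved, so
  pretraining should help;
* `null` — effect 0 (30 ROIs, 100 subjects): the leakage control;
* `deep_vs_shallow` — planted within-DMN plus between-DMN-FPN edges, 2
  sites of 40+40, so part of the signal lives in cross-network
  interactions that the deeper layer's larger receptive field captures.

Cohort sizes were chosen as the smallest that keep the tested statistics
stable (e.g. 160 subjects for elementwise t maps); the test suite and the
acceptance script use hidden size 16 and 60–100 epochs, which the pilot
runs showed is past convergence for these problem sizes.

## Known limitations

* At the stock learning rate (1e-4), very small training sets (tens of
  subjects) give the optimizer only a few hundred steps in 100 epochs;
  single-run training accuracy is then seed-dependent even on separable
  data. The protocols average over folds and seeds for this reason.
* Per-fold AUC on small transfer test folds (4 subjects) is coarse;
  fold-averaged AUC should be read with that granularity in mind.
* The leave-site-out protocol cannot harmonize the held-out site (by
  construction); its accuracy therefore mixes model generalization with
  raw site shift.
* `KnnGraph` similarity weights floor negative similarities at zero to
  keep the renormalized operator's nonnegativity; with the default binary
  weights this never triggers.
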