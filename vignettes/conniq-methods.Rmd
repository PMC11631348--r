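---
title: "Methods: interpretable prediction of intelligence from multi-state functional connectivity"
author: "conniq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable prediction of intelligence from multi-state functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(conniq)
```

# Scope and model

`conniq` implements an interpretability-first pipeline for predicting
individual intelligence components from functional brain connectivity
(FC) measured during multiple cognitive states. The pipeline has six
stages, each exposed as package functions and exercised end to end on a
synthetic cohort generator with planted ground truth:

1. **Psychometrics.** Three intelligence components are estimated from a
   battery of 12 cognitive measures: general intelligence *g* as the
   general factor of an exploratory bifactor model, fluid intelligence
   *gF* as a single-factor EFA score over seven fluid-defining tasks,
   and crystallized intelligence *gC* as the sum of two standardized
   test scores (vocabulary, reading recognition).
2. **Connectivity.** Per-state FC is the Fisher-z transformed Pearson
   correlation between node time series; the two phase-encoding runs
   are averaged on the z scale. Two additional *latent FC* states are
   derived by connection-wise one-factor analysis across states (one
   across rest plus all tasks, one across tasks only).
3. **Connection selection.** Edge masks with explicit provenance:
   whole-brain; within-network; between-network; all-but-one-network;
   one network plus all its between-network edges (for seven networks,
   1 + 7 + 21 + 7 + 7 = 43 selections, hence 10 states x 43 selections
   = 430 model configurations per component); theory-driven node sets
   mapped by smallest Euclidean distance from published cluster
   coordinates; random-edge and random-node null selections; and
   relevance-based top-k selections.
4. **Prediction.** Family-aware stratified 5-fold cross-validation;
   out-of-sample deconfounding (confounds regressed out of target and
   features with training-fitted coefficients and standardization);
   feedforward ReLU networks (1–3 hidden layers of 10/50/100 units,
   dropout 0.25, MSE loss, learning rate 0.01, early stopping with
   patience 100 up to 20,000 epochs), with the architecture chosen by
   an inner 3-fold search; performance as Pearson r(y, y-hat) plus
   MSE/RMSE/MAE on range-normalized scores.
5. **Relevance.** Layer-wise relevance propagation (epsilon rule) and
   the *stepwise* variant: train on all edges, attribute on training
   data, remove the top block, retrain — yielding a full edge priority
   ordering.
6. **Inference.** Permutation tests of performance (null models trained
   on shuffled scores) and of model differences (paired runs on the
   same shuffled scores), both on the Fisher-z scale with the
   (b+1)/(m+1) estimator; paired t-tests for multi-model comparisons;
   Benjamini–Hochberg FDR; and graph-metric characterization of
   relevant edges (participation coefficient, within-module degree
   z-score, retest ICC) against random edge sets.

# The synthetic cohort generator

The generator (`generateCohort`, `generateConnectomes`) defines the
study conditions for every test in the package.

**Latent components.** A trivariate normal with target correlations
0.78 (g–gC), 0.76 (g–gF), 0.49 (gC–gF). A family-shared component
(default 30% of variance) induces family clustering; family sizes
follow a truncated geometric distribution (most families of size 1–3).
The crystallized and fluid *group* latents used by the measurement
model are the standardized residuals of gC and gF on g, which
reproduces the full 3 x 3 target correlation matrix exactly in the
population.

**Confounds.** Age, sex, handedness, mean framewise displacement, and
spike proportion are built from standard-normal channels correlated
with g at −0.13, 0.18, 0.00, −0.20, −0.20 respectively, then mapped to
natural units (years; 0/1 via a latent threshold with the point-biserial
attenuation factor compensated; uniform [−100, 100] via a Gaussian
copula; mm with a floor at 0.005; a fraction clamped to [0, 1]). Motion
exclusion applies mean FD < 0.2 mm, spike proportion < 20%, and max
spike ≤ 5 mm.

**Measures.** Each of the 12 measures is loadings x latents + Gaussian
noise: a general loading on g for all, a fluid group loading for the
seven fluid tasks, a crystallized group loading for the two
crystallized tests. The default loadings (0.68/0.72/0.75 general;
0.35 fluid; 0.55 crystallized) were fixed *a priori* by closed-form
factor-model arithmetic: with equal loadings λ on k indicators, the
regression-score validity is sqrt(kλ²/(1 − λ² + kλ²)), and combining
this with the alignment between the indicator common direction and the
target latent predicts recovery correlations of about 0.92 (g), 0.96
(gC), and 0.92 (gF) — above the floors (0.9/0.95/0.85) the package
asserts.

**Connectomes.** Edge values are base mean (network-structured:
within-network edges higher) + planted signal + confound leakage +
Gaussian noise. Planted edges carry β x (state signal scale) x a
*block latent*; blocks group planted edges that share one hub node and
mix the target component with block-specific noise
(`redundancyNoise`, default 0.3). This hub-block structure is what
makes the generator reproduce two qualitative findings: selections can
*compensate* for removed blocks (partial redundancy), and random-edge
selections outperform random-node selections at matched edge count,
because a node-induced subgraph resamples few blocks (redundant
information) whereas scattered edges average block noise away.
Confound leakage is additive and linear, so the linear deconfounder has
a true target. State signal scales default to a demanding-task-high
profile (working memory and language 1.0, emotion 0.25), emulating the
observed state dependence of prediction performance.

**What the generator does not emulate.** BOLD hemodynamics, scanner
noise spectra, task timing, spatial autocorrelation of parcels,
non-Gaussian FC tails, and any empirical HCP distribution beyond the
moments above. Passing tests therefore demonstrate correctness of the
pipeline's logic and calibration of its inference under the stated
conditions — not effect sizes on real neuroimaging data, where
whole-brain performance is far lower (r ≈ 0.2–0.3).

# Numerical and design choices

* **Bifactor estimation** is exploratory (two-stage EFA with
  Schmid–Leiman orthogonalization), not confirmatory SEM: first-stage
  ML factor analysis (`stats::factanal`) with an oblique promax
  rotation (promax is the oblique rotation available in base R; with a
  single factor — the gF model — rotation is a no-op and the configured
  name is only recorded), a single second-order factor of the factor
  correlations, then Schmid–Leiman. Factor scores use the regression
  (Thurstone) method; a tiny ridge (1e-8) keeps the correlation-matrix
  inverse defined in degenerate batteries, and a rank-1 battery
  short-circuits to the common vector. The group-factor count defaults
  to 4 and is configurable. Sign conventions: majority of general
  loadings non-negative; per-factor salient loadings positive; mean
  latent-FC loading positive.
* **Degenerate correlations.** |r| ≥ 1 − 1e-7 is clipped before the
  Fisher transform with a warning; constant time series are rejected
  with the node id.
* **Per-edge latent FC** uses ML factor analysis with a principal-axis
  fallback on non-convergence; zero-variance edges are flagged and
  fall back to the standardized state mean.
* **Retest ICC** is ICC(2,1): two-way random effects, absolute
  agreement, single measurement — the standard retest choice.
* **Fold stratification** sorts families by family-average target and
  deals consecutive blocks of `nFolds` families by a seeded random
  permutation; early-stopping validation subsets are family-aware.
  Early stopping compares against the best-so-far validation loss with
  patience 100 (the alternative reading, comparison against the loss
  100 epochs ago, is looser and was not chosen).
* **Training** is full-batch gradient descent (cohort-scale data fits
  in memory; mini-batches are configurable), He initialization, seeded
  per (fold, repetition). Repetitions ("varying stratified folds") are
  fold seeds.
* **RNG discipline.** Every seeded function evaluates under a local RNG
  stream and restores the caller's state, so seeded components can be
  nested inside permutation loops without making successive shuffles
  dependent.
* **LRP** uses the epsilon rule (ε = 1e-6) on all linear layers;
  dropout is inactive at attribution time; attribution inputs are
  training-fold subjects only. Ranking is by absolute mean relevance
  (signed values are retained for reporting); ties break by edge
  index. The default stepwise schedule removes the top 1% of remaining
  edges per round (minimum 10); aggregation across folds/repetitions
  uses mean relevance, or mean rank when explicit orderings are
  aggregated.
* **Permutation inference** shuffles targets before deconfounding and
  fold construction, so the null preserves the full pipeline; p-values
  use the plus-one estimator and are never exactly zero. The
  model-difference test pairs both pipelines on identical shuffles.
  Graph metrics are computed on weighted matrices by default
  (binarized input is accepted); zero-strength nodes get PC = 0 and
  modules with zero within-degree SD get z = 0, both flagged.
* **Edge indexing** is 1-based, row-major over the strict upper
  triangle; the convention is recorded in every sidecar.
* **Interfaces.** This is an analysis package: the exported functions
  (`runExperiment`, `splitLockbox`, the writers) are the orchestration
  surface; no shell entry point is shipped.

# Problem sizes used by the test suite

The package's own checks run at desk scale, chosen to finish in
minutes while leaving clear signal margins: cohort-moment checks at
n = 5000; psychometric and latent-FC recovery at n = 2000; stepwise-LRP
recovery on 21-node (210-edge) connectomes with 20 planted edges at
strong signal (n = 300, 10 seeds); the selection-ordering experiment on
a 40-node (780-edge) connectome with 300 weak, widely distributed
planted edges in strongly redundant hub blocks (block-specific variance
share 0.8, n = 350) — the "distributed signal" regime in which
performance grows with the number of selected connections, and in which
scattered random edges beat node-induced subgraphs because they cover
more signal blocks (at low block redundancy the two null selections are
equivalent by symmetry: their expected planted-edge overlap is
identical); and
permutation-test calibration with a fast linear cross-validated runner
(200 replicates at reduced permutation counts), since type-I
calibration of the permutation machinery does not depend on the
regressor inside. In the ordering experiment the relevance ranking is
estimated on the analysis sample itself (as in the study design, where
rankings come from training folds of the same sample); the random-edge
and random-node references are independent of the data, so the
comparison of interest is unaffected.

# Known limitations

* The exploratory bifactor route can differ from confirmatory bifactor
  SEM scores when group factors are highly correlated; Heywood cases
  are flagged, not repaired.
* Full-batch gradient descent with a fixed learning rate is adequate
  for the cohort sizes here but has no adaptive scheduling; divergence
  aborts with a diagnostic rather than retrying.
* The epsilon-rule relevance is conservative only up to epsilon leakage
  and, with biases, deliberately reports the leaked share rather than
  renormalizing.
* The generator's confound leakage is linear; nonlinear confounding
  would not be removed by the linear deconfounder (by design, matching
  the pipeline under study).
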