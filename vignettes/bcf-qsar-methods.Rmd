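---
title: "Modelling bioconcentration factors from molecular descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bioconcentration factors from molecular descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcfqsar)
```

## The problem

The bioconcentration factor (BCF, L kg⁻¹) measures how strongly a
waterborne chemical accumulates in an organism at steady state. Hazard
frameworks such as REACH classify chemicals as not bioaccumulative (nB),
bioaccumulative (B, BCF > 2000) or very bioaccumulative (vB,
BCF > 5000), and measuring BCF experimentally means long, costly animal
exposure studies. QSAR models replace the measurement with a prediction
of log₁₀ BCF from molecular descriptors — numeric summaries of a
molecule's constitution (atom counts, molecular weight), topology
(branching and shape indices, polar surface area), electrotopological
state and physico-chemistry (the pH-dependent octanol–water distribution
coefficient logD).

`bcfqsar` implements that workflow end to end: descriptor-table
preparation, wrapper feature selection monitored by a generalized
regression neural network, neural and baseline regressors, a
PCA applicability domain, error-ratio sensitivity analysis, and category
level classification. This vignette records the models, the assumptions
and the design choices.

## The synthetic data generator

Curated BCF datasets cannot be redistributed with the package, so every
stage is exercised on a generator that emulates the statistical features
such data present to a modelling pipeline:

* **Correlated descriptors.** A latent multivariate-normal draw with a
  planted correlation structure; by default the four strongly collinear
  descriptor pairs observed in real descriptor matrices for this problem
  (MW–SPI r = 0.794, MW–Ram 0.696, Ram–SPI 0.787, STN–HNar 0.748). Each
  latent column is mapped through a monotone linear transform to a
  plausible range (MW ≈ 300 ± 120 Da, TPSA ≈ 70 ± 35 Å², …); atom counts
  are rounded to non-negative integers and TPSA is clipped at zero. The
  monotone transform preserves the planted correlations for continuous
  columns; rounding perturbs them only marginally.
* **A saturating hydrophobicity effect.** Accumulation grows with
  hydrophobicity but flattens at high logP/logD (above roughly 6), so
  the default response takes `logD` through a capped-linear ramp
  `f(x) = slope · (x − s·log(1 + exp((x − loc)/s)))` with slope 0.6,
  location 6 and scale 1: slope ≈ 0.6 per log unit well below the
  location, decaying smoothly to 0 above it. A logistic sigmoid was
  considered and rejected: its increments are symmetric about the
  location, so the increment from logD 7→8 would *exceed* that from
  3→4, which is the opposite of the saturation the effect is meant to
  encode. Weak linear contributions of TPSA (−0.01 per Å²), nitrogen
  count (−0.15) and MW (+0.002 per Da) complete the deterministic part.
* **Noise.** Gaussian with sd 0.6 log units by default — inside the
  0.42–0.75 log-unit band that inter-study experimental BCF variability
  spans. This treats experimental variability as a plausible noise
  scale, not as a fitted residual estimate.
* **Hydrophobic-heavy chemistry.** `logD` is centred at 4 (sd 2.5):
  fish BCF training sets are dominated by PCBs, PAHs and
  organochlorines, so real datasets place substantial mass above the
  saturation threshold. About a fifth of generated compounds have
  logD > 6.
* **Outliers.** An optional fraction of rows is shifted by a chosen
  number of per-descriptor standard deviations along a random direction,
  with the shifted ids returned as ground truth for
  applicability-domain tests.

What the generator does *not* emulate: discrete chemical-class structure
(pigments vs. pharmaceuticals), pKa-dependent speciation, or any real
descriptor-descriptor nonlinear dependence. Passing tests therefore
demonstrate that the algorithms recover planted structure under
realistic dimensions, collinearity and noise — not that the models reach
any particular accuracy on real chemistry.

## GRNN: the feature-selection monitor

The generalized regression neural network is Nadaraya–Watson kernel
regression: training stores the exemplars; prediction is

$$\hat y(x) = \frac{\sum_i y_i\, e^{-d_i^2/2\sigma^2}}{\sum_i e^{-d_i^2/2\sigma^2}},$$

with $d_i$ the Euclidean distance to exemplar $i$ and a single isotropic
bandwidth $\sigma$ in standardized-descriptor units (no per-dimension
smoothing — the classical formulation, and cheap enough to score
thousands of subsets). Predictions are convex combinations of training
targets, so they can never leave the observed target range. Weights are
stabilized by factoring out the nearest exemplar's kernel value, so a
far query degrades gracefully to its nearest neighbour instead of 0/0.

The bandwidth is chosen on a holdout set from a log-spaced grid
(0.05–2.0, 20 points, an implementation choice); ties break toward the
larger, smoother bandwidth. For pure-noise targets the selected
bandwidth migrates to the smooth end of the grid, as it should — though
with a finite holdout the RMSE profile is nearly flat across the largest
bandwidths, so "the maximum exactly" is only majority behaviour, not a
certainty.

## Wrapper feature selection

`subset_fitness()` scores a candidate descriptor subset by the
verification RMSE of a GRNN fitted on the training rows (bandwidth
re-selected per subset). Two search strategies consume it:

* **Genetic algorithm** over bitmask chromosomes. Defaults follow the
  study settings: population 500, 250 generations, mutation rate 0.1,
  crossover rate 1.0. Where the original description is silent the
  package uses standard choices: tournament selection of size 3, uniform
  crossover, elitism 2, and a patience rule (stop after 25 generations
  without improvement) as the concrete reading of "stop when the error
  shows no improvement". Mutation rate 0.1 is interpreted as a
  per-chromosome probability of flipping one random bit — applying 0.1
  independently per bit on a ~180-descriptor chromosome would randomize
  18 bits per child and destroy convergence; `per_bit = TRUE` restores
  the literal reading. The verification-set GRNN error (not a
  cross-validated one) is the fitness, keeping the monitor fast. A
  `"ci"` preset (population 60, 40 generations) is used throughout the
  tests; both presets are configurations of the same algorithm.
* **Stepwise search**, forward and backward, with a patience of 2
  non-improving steps. On data with one dominant descriptor both
  directions converge to the same subset — reproduced as a test.

`curate_subset()` appends forced-in descriptors (e.g. logD, kept for its
demonstrated influence on accumulation regardless of what the search
picks) order-stably.

## Learners

* **MLP.** 3- or 4-layer perceptrons: tanh hidden layers, a linear
  output unit, full-batch mean-squared-error loss. Two trainers:
  `"bp"` — plain gradient descent with a fixed learning rate — and
  `"cgd"` — Polak–Ribière conjugate gradients with Armijo backtracking
  line search (the concrete reading of "conjugate gradient descent";
  batch size, learning rate and initialization are not specified in the
  original description, so full-batch training, small uniform
  fan-in-scaled initialization and a seeded RNG are the package's
  choices). Training runs 100 iterations; early stopping is a
  checkpoint restore of the iteration with minimum verification RMSE
  (patience defaults to infinity, i.e. the full budget is always
  trained; the restored model's verification error equals the minimum
  of the training log by construction). The reference architecture is
  `hidden = c(14, 10)`: a 4-layer network with 14 inputs, hidden layers
  of 14 and 10 nodes, and one output.
* **Standardization.** Inputs are centred and scaled by training
  statistics by default for the MLP, RBF, kNN and GRNN. Raw descriptor
  scales (MW in hundreds of Da next to dimensionless indices near 1)
  saturate tanh units and distort isotropic distances, so the package
  treats input scaling as part of these models; `standardize = FALSE`
  restores raw-scale training. OLS is scale-equivariant and is fitted
  raw so its coefficients live on the descriptor scale.
* **RBF.** k-means centres on the standardized training descriptors,
  widths set to each centre's nearest-centre distance, output weights by
  ridge-regularized least squares (penalty 1e-8). With one centre per
  training point the network interpolates; with one centre it degrades
  to a single bump over an output bias.
* **Baselines.** OLS via QR with a rank check (singular designs are
  refused with a pointer to ridge); ridge in centred/standardized
  coordinates with an unpenalized intercept; kNN with uniform or
  inverse-distance weights.
* **Cross-species retraining.** `retrain_cross_species()` rebuilds the
  same architecture and descriptor set with fresh weights and trains it
  on a new species' table — no weight transfer. With identical data and
  seed it reproduces direct training exactly.

## Applicability domain

PCA is computed on standardized training descriptors (correlation-matrix
PCA — descriptor units are incommensurate). The domain statistic is the
squared Mahalanobis distance in the space of the components covering 95%
of variance, $\sum_j s_j^2/\lambda_j$, which is approximately
$\chi^2_k$-distributed for cases from the training distribution; the
out-of-domain threshold is the 0.975 quantile of $\chi^2_k$. The 95%
default and the use of retained components only are reconstructions —
the distance metric and component count are not fixed by the original
description — chosen because they make the $\chi^2$ threshold
distributionally coherent: under the null the flag rate calibrates to
2.5%, which the tests verify on 10,000 fresh draws.

Distance-based domains have a documented blind spot: the model does not
use all descriptors equally, so a case can sit outside the domain yet be
predicted well (an excursion along a direction the model ignores) or sit
inside it and be predicted badly (label noise). Both discordant cases
are constructed explicitly in the test suite.

## Sensitivity analysis

The importance of descriptor $j$ is its error ratio: RMSE after
degrading $j$, divided by baseline RMSE, on the verification + test rows
(importance should reflect generalization error; the evaluation subset
is configurable). Degradation has two modes because "removing a
descriptor from the model" admits two readings: `"mean_substitution"`
(default) freezes the trained model and replaces the descriptor column
with its training mean — a descriptor with exactly zero influence scores
exactly 1 — and `"retrain"` refits the architecture without the
descriptor. Rankings are sorted by decreasing ratio with alphabetical
tie-breaks, so reports are deterministic. Because degrading one member
of a collinear pair leaves its partner carrying the shared signal, any
descriptor in a pair with |r| > 0.65 is annotated and a warning is
raised; ratios for such descriptors should be read with caution.

## Assessment and classification

R² is the squared Pearson correlation between observed and predicted
values — this matches the "correlation coefficient" convention and
differs from $1 - SS_{res}/SS_{tot}$ for biased predictors, which is
why the choice is stated explicitly. RMSE ≥ MAE always (Jensen).
`repeated_kfold()` implements 10-fold cross-validation repeated 5 times
(50 fold evaluations) for tuning-style resampling.

`pbt_classify()` maps logBCF to nB/B/vB with boundaries at BCF 2000 and
5000 L kg⁻¹ (REACH Annex XIII defaults; the thresholds are parameters
because they are regulatory conventions, not properties of the data). A
BCF exactly at a boundary is assigned to the lower category; the
comparison is done on the log scale to make that convention exact in
floating point. `classification_report()` counts a false negative when
the true category is higher than the predicted one (hazard
under-prediction) and a false positive for the reverse; correct + FN +
FP = 1 by construction.

## Numerical choices and degenerate inputs

* GRNN weights use a subtract-the-minimum-distance stabilization; the
  bandwidth grid is strictly positive; σ ≤ 0 is an error.
* GA all-zero chromosomes are repaired by activating one random bit, so
  the empty subset is never scored.
* MLP divergence (non-finite loss) aborts with a diagnostic rather than
  returning garbage; the CGD line search falls back to steepest descent
  when no Armijo step is found.
* Zero-variance descriptors are an error at standardization and AD
  fitting time — they must be removed by `clean_descriptors()` first.
* Splits take explicit counts because published designs (242/55/55 of
  352) are not exact fractions; `default_split_sizes()` floors the
  verification/test fractions and gives the remainder to training. How
  the original 242/55/55 assignment was randomized is unknown; the
  package uses simple (unstratified) random splits.
* Missing descriptor cells: strict mode (default) errors, lenient mode
  drops the affected rows with a warning. The logD pH is carried as
  table metadata (default 7.0, the usual compromise when experimental pH
  is only known as a range).

## Problem sizes used in tests

The suite runs the algorithms at reduced but structurally faithful
sizes, chosen so the whole suite completes in a few minutes: GA recovery
uses the `"ci"` preset on 20-descriptor tables (n = 400) over 10 seeds;
the exhaustive-search comparison enumerates all 1023 subsets of
10-descriptor tables (n = 150); applicability-domain calibration uses
2000 training and 10,000 evaluation draws; MLP-vs-OLS comparisons use
n = 400 with 10 seeds. The full-scale GA preset (500 × 250) is the
package default for real analyses.

## Known limitations

* The GRNN bandwidth is isotropic; descriptors that matter little still
  dilute the distance, which is precisely why feature selection precedes
  it.
* The error ratio inherits the collinearity caveat above; it indicates,
  it does not prove, mechanistic importance.
* The applicability domain is a global ellipsoid in PC space; it cannot
  represent disjoint chemical-class clusters.
* The synthetic generator's additive-effects response cannot measure
  real-data accuracy; results on it bound what the pipeline can recover
  under its stated assumptions, nothing more.
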