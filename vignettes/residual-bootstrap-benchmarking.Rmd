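---
title: "Residual-bootstrap benchmarking of prediction methods for discharge blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual-bootstrap benchmarking of prediction methods for discharge blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpbench)
```

## The problem

Comparisons of prediction methods on a single clinical dataset confound two
things: how good a method is, and how well the dataset's true outcome
mechanism happens to match that method's inductive bias. `sbpbench`
implements a *neutral* comparison design for a continuous outcome (systolic
blood pressure at hospital discharge, mmHg): each of six candidate methods
takes a turn as the data-generating process (DGP) that all six are then
evaluated on. No method is privileged, and because the generating method is
known, relative performance can be read against a known truth.

The six methods are linear regression estimated by ordinary least squares
with restricted cubic splines for continuous predictors (`ols_rcs`), the
lasso and ridge regression, gradient-boosted regression trees, random
forests, and a feed-forward neural network with a single hidden layer.

## Synthetic cohorts

The patient-level source data (hospitalized AMI and CHF cohorts) are
access-restricted; only marginal summaries are published. The package
therefore ships *cohort configurations* — per-variable marginals for the
derivation and validation samples — and synthesizes stand-in cohorts from
them:

* **Gaussian copula.** A latent multivariate normal `Z` with a configured
  correlation is drawn; continuous column `j` becomes `mean_j + sd_j z_j`,
  binary column `j` becomes `1(z_j > Φ⁻¹(1 − prevalence_j))`. Marginals are
  matched exactly in expectation; inter-predictor dependence is inherited
  from the latent scale.
* **Correlation default.** The published tables contain no inter-predictor
  correlations, so any choice is a stand-in, not an estimate. The default is
  exchangeable with latent ρ = 0.2 — enough dependence that penalized and
  greedy methods behave differently from the independent case, while
  remaining positive-semidefinite for any number of predictors. A full
  correlation matrix can be supplied instead, and ρ is validated against the
  exchangeable PSD bound `(−1/(p−1), 1)`.
* **Marginal shape.** Continuous variables are generated Gaussian even where
  real labs (e.g. creatinine) are right-skewed. The framework's comparisons
  are driven by the outcome mechanism, not marginal shape, so the simpler
  choice was preferred; skewness is a known limitation below.
* **Suppressed cell.** The AMI validation prevalence of cardiogenic shock
  was suppressed at source (cell count ≤ 5, i.e. ≤ 0.11%); it is imputed at
  0.5% — the derivation value rounded down to a plausible small prevalence —
  and carries an `imputed: TRUE` provenance flag in the configuration.

### The calibrated reference outcome

The real study fits models to observed outcomes; the synthetic study needs a
known ground truth. `calibrate_outcome_model()` builds a linear truth on
internally standardized predictors whose generated outcome matches the
published outcome marginal (e.g. 120.40 ± 19.69 mmHg for the AMI derivation
sample) and whose linear predictor carries a chosen **signal fraction** of
the outcome variance:

* raw coefficients (reproducibly drawn standard normals, or user-supplied)
  are rescaled by one common factor so `var(lp) = sf · target_sd²`;
* the intercept centres the outcome at `target_mean`;
* `noise_sd = target_sd · sqrt(1 − sf)`.

The signal fraction is therefore the theoretical R² ceiling of the synthetic
truth. The default `sf = 0.2` was chosen to sit in the range typically
reported for predicting blood pressure from admission characteristics in
hospitalized cohorts — explainable fractions around a fifth of the outcome
variance; `sf = 0` gives a pure-noise cohort and is used as a negative
control in the tests.

### What the generator does and does not emulate

It emulates: mixed continuous/binary tables with realistic marginals and
non-trivial correlation, distinct derivation/validation marginals (temporal
drift), and an outcome with a controlled explainable fraction. It does not
emulate: skewed or heavy-tailed labs, nonlinear or interaction structure in
the *true* outcome (the reference truth is linear — the nonlinear methods'
generating behavior enters through the anchored DGPs instead), missing
data, or any attempt to reconstruct real subjects. Passing tests therefore
validate the machinery and its statistical contracts, not claims about any
real cohort.

## The learners

All six share one `fit_learner()`/`predict()` contract with a fixed column
schema; stochastic elements (forest bootstrap, optional boosting
subsampling, network initialization) are governed by an explicit seed, so
identical inputs give identical predictions.

* **`ols_rcs`.** Each continuous predictor is expanded by a restricted cubic
  spline basis written in-package: `k` knots give `k − 1` columns — the
  identity plus truncated-cubic terms constrained so the function is linear
  beyond the boundary knots, scaled by `(t_k − t_1)²`. Knots sit at the
  conventional quantiles (0.10/0.50/0.90 for `k = 3`, up to
  0.025/0.1833/0.3417/0.50/0.6583/0.8167/0.975 for `k = 7`). Binary
  predictors enter untransformed — the configuration marks variable kinds
  explicitly so indicators are never splined. The fit is unregularized least
  squares via QR; rank deficiency and `n ≤ p` raise errors rather than being
  silently regularized. `σ̂² = RSS/(n − p)` (the unbiased denominator; the
  choice matters only as the Gaussian residual scale of the OLS-anchored
  DGP).
* **`lasso` / `ridge`.** `glmnet` fits with the penalty applied to
  standardized predictors and an unpenalized intercept; coefficients are
  reported on the original scale. A fit stores a short descending λ path
  ending exactly at the requested λ so prediction uses a computed point.
* **`boosted_trees`.** Stagewise regression trees on the squared-error
  gradient via `xgboost`: depth = `interaction_depth`, shrinkage =
  `learning_rate`, `n_trees` fixed at 100 by default with no early stopping,
  no leaf regularization (`lambda = 0`), base score = `mean(y)`, and
  `subsample = 1` by default so boosting is deterministic (a subsample
  option exists for sensitivity analysis). Note the depth semantics: here
  `interaction_depth` is the maximum tree depth; implementations that count
  splits per tree will differ for the same nominal value.
* **`random_forest`.** `randomForest` with `mtry` candidate variables per
  split, `min_node_size` leaf floor, and 500 trees by default. Split-tie
  behavior is the backend's own.
* **`nnet1`.** One hidden layer of `hidden_units` logistic units with a
  linear output unit and L2 `weight_decay`, fit by quasi-Newton (BFGS) with
  at most 500 iterations and tolerances 1e−8. Inputs are standardized (the
  weight-decay penalty is scale-sensitive); initial weights are drawn
  Uniform(−0.5, 0.5) from the seed, one start. Non-convergence is recorded
  on the fitted object, and a failed fit inside the simulation becomes a
  logged missing record, never a silent zero.

## Tuning

Hyperparameters are tuned **once on the base data and frozen** across all
simulation replicates; re-tuning inside each replicate would change the
estimand from "method as configured" to "method plus its tuning procedure"
and multiply cost a thousand-fold. The tuned values for the packaged cohorts
ship as defaults (`default_hyperparameters()`), e.g. AMI: boosted trees
depth 4, rate 0.065; forest mtry 6, node size 20; OLS 3 knots; network 5
units, decay 0.05; lasso λ = 0.08596; ridge λ = 0.56553.

* **Grid search.** Tenfold CV maximizing the squared-Pearson R² (the same
  metric as final evaluation, for uniformity), with one fold assignment
  fixed for the whole search so grid points are compared on identical
  splits; ties go to the earliest declared point. Folds are unstratified —
  the outcome is continuous. Default grids: network 2..15 units × decay
  {0, 0.01, 0.05, 0.1, 0.5}; boosting depth 1..5 × rate {0.005, 0.01, 0.035,
  0.065, 0.1}; forest mtry ⌊p/6⌋..⌊p/2⌋ × node size {5, 10, 20, 50}; OLS
  knots 3..6. The tree/forest ranges bracket the shipped tuned values.
* **λ path.** `select_lambda()` builds a 100-point log-spaced path from
  `λ_max = max |⟨x_j, y − ȳ⟩|/n` (standardized predictors; the smallest λ
  with all lasso slopes zero) down to `10⁻⁴ λ_max`, with the conventional
  ×1000 scaling of `λ_max` for ridge, and returns the λ minimizing tenfold
  CV MSE. Minimum-CV was chosen over the 1-SE rule as the plain reading of
  "optimal"; `one_se = TRUE` is available. Exact CV ties (which occur on
  the flat all-zero top of a null-signal lasso path) resolve toward the
  larger penalty.

## The data-generating processes

`build_dgp()` fits the anchor **exactly once** on the base derivation
sample, freezes its predictions on both samples, and stores the residual
source: the empirical pool `y − ŷ` of derivation residuals, or
`N(0, σ̂²)` for the OLS anchor. The validation sample is bootstrap-expanded
to 100,000 rows by default (5,000 in the desk preset) before prediction;
since prediction is rowwise, expansion and prediction commute and the
expanded predictions are exact copies of source-row predictions.

`simulate_pair()` then draws, independently for the derivation and
validation samples, i.i.d. residuals per subject and adds them to the frozen
predictions. Design choices worth stating:

* **Covariates are frozen** across replicates; only outcomes are
  re-simulated. Replicate-to-replicate variation therefore isolates outcome
  noise, the quantity the error bars summarize.
* **Validation residuals come from the derivation pool** by default — the
  pool is only defined where outcomes were observed. Whether a separate
  validation pool is preferable is genuinely ambiguous; `build_dgp()` takes
  `validation_residuals = "validation"` (with base validation outcomes) as
  the alternative.
* **Residual draws are i.i.d.** per subject and replicate; no blocking,
  stratification, or covariate-dependent residual structure.
* Replicate `r` uses the seed substream `(base_seed, r)`, so any subset of
  replicates can be regenerated bit-identically in isolation, and the
  streaming callback interface of `generate_replicates()` avoids holding
  1000 pairs in memory.

The DGP's **signal proportion** `var(ŷ_valid)/(var(ŷ_valid) + var(e))` is
the oracle R² ceiling: the anchor's own frozen predictions attain it in
expectation. A *refit* of the anchor on a simulated derivation sample sits
systematically below the ceiling — with `p` parameters and `n` training
rows the attenuation is approximately `var(ŷ)/(var(ŷ) + (p/n)σ²)` — which
is why the test suite checks the ceiling two-sided against the anchor's own
predictions and one-sided (as a bound) against the per-replicate refit.

## Evaluation

R² is the squared Pearson correlation between observed and predicted
outcomes — association, not agreement; it is invariant to affine
recalibration of the predictions and is reported as a proportion. MSE and
MAE are plain averages of squared and absolute errors (mmHg² and mmHg);
Jensen's inequality `MAE² ≤ MSE` is asserted globally in the tests.
Summaries are means and SDs (n − 1 denominator, the usual sample SD) over
replicates per (DGP, method, metric); failed fits are excluded from means
but counted. An `intercept_only` diagnostic learner is included: its R² is
undefined (constant predictions) and is recorded as `NA` with a warning, and
its MSE estimates the simulated outcome variance.

## Numerical choices and degenerate inputs

* Prevalence 0 or 1 maps to a threshold at ±∞, giving exact constant
  columns; a continuous sd of 0 gives a constant column at its mean.
* A constant linear predictor with positive requested signal fraction is an
  error (the calibration has no solution).
* Zero-variance held-out outcomes or predictions make fold R² undefined; CV
  records 0 with a warning (so a degenerate grid point loses rather than
  poisons the search), while top-level `r2_pearson()` raises an error and
  `evaluate_replicate()` records `NA`.
* The copula factor uses an eigendecomposition with eigenvalues clipped at
  0 (tolerance −1e−8), so positive-*semi*definite correlation matrices are
  accepted.
* Seed substreams are derived as
  `(|seed|·48271 + |key|·8191 + 1) mod (2³¹ − 19)`, keeping every derived
  seed a valid 32-bit integer; string labels hash by position-weighted
  code-point sum.
* Serialized learners are versioned; the boosted-tree handle is stored as
  raw model bytes so round-trips survive sessions.

## Problem sizes in the shipped tests

The test suite and the acceptance checks run the framework at reduced sizes
chosen to exercise every contract while keeping a full run in the tens of
seconds: marginal-recovery and calibration checks at n = 50,000; the
factorial pipeline at 2 anchors × 3 methods × 5 replicates; the oracle
ceiling and coefficient recovery on an OLS-anchored DGP at n_deriv = 1,000,
expand_to = 5,000, with 50 and 200 replicates respectively. The full design
(6 × 6 × 1000, expansion 100,000) is what `study_config()` defaults to and
runs unchanged — only slower.

For the coefficient-recovery check, the per-coefficient "within 2 Monte
Carlo SEs" rule is applied jointly: with 46 coefficients, roughly two
exceedances are expected under exact unbiasedness, so the test bounds the
exceedance count by the 99.9% binomial envelope of the 2-SE rule rather
than demanding 46 simultaneous passes.

## Known limitations

* Synthetic cohorts match published marginals and a chosen latent
  correlation, not the real joint distribution; conclusions about the real
  cohorts require the real data.
* The linear reference truth makes the empirical comparison favorable to
  linear methods by construction; method-anchored DGPs are the intended
  route to nonlinear truths.
* `interaction_depth` semantics differ across boosting implementations
  (depth here, splits elsewhere); comparisons across implementations should
  match on realized tree complexity.
* The neural-network backend offers logistic hidden units only; a fully
  linear hidden layer (equivalent to a penalized linear model) is not
  available.
* R² based on squared correlation rewards discrimination but not
  calibration; a method with systematically biased but well-ordered
  predictions scores well on R² while its MSE suffers.
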