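---
title: "Modelling pharmaceutical sorption to sewage sludge: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pharmaceutical sorption to sewage sludge: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorbkd)
```

## The modelling problem

The sludge/water partition coefficient `Kd = [API]_sludge / [API]_aqueous`
(L kg⁻¹) summarises how strongly a pharmaceutical sorbs to sewage sludge.
Literature compilations of measured K_d values are small (a few hundred
measurements), heterogeneous (different sludges, pH, protocols; the same
compound can span more than two log units across studies) and strongly
structured by the charge state of the dominant species near pH 7.4:
hydrophobicity (log K_ow) predicts sorption moderately for uncharged and
positively charged compounds and essentially not at all for anions.

`sorbkd` implements the complete QSPR workflow for such data: descriptor
reduction, linear reference models (univariate, stepwise, PLS) with the
field's standard fit statistics, and Bayesian-regularised neural-network
committees with automatic relevance determination (ARD). Because real
descriptor sets for this problem come from commercial software, the
package ships a synthetic-data generator that reproduces the *statistical
shape* of such a compilation with known ground truth, so every stage of
the pipeline has a parameter-recovery test.

## Descriptor reduction

Two unsupervised steps precede any model fit:

1. **Coefficient-of-variation filter** (`cv_filter()`): descriptors with
   `|sd / mean| < 0.05` carry almost no relative variation and are
   removed. The absolute value of the mean is used so a descriptor's sign
   convention cannot flip the decision. Columns whose mean is numerically
   zero have an effectively infinite CV and are kept, unless their
   standard deviation is also ~0, in which case they are removed as
   constants.
2. **Unsupervised forward selection** (`ufs_select()`): starting from the
   pair of descriptors with the smallest absolute pairwise correlation,
   the candidate whose squared multiple correlation (R² of its
   least-squares regression, with intercept, on the selected set) is
   smallest is added at each stage, provided that R² stays below
   `r2_max` (default 0.99, exposed in `run_config()`; published
   applications rarely state their cutoff, and this is the main knob
   controlling the reduced set size). Ties are broken by the smallest
   column index so the procedure is deterministic. The multiple R² is
   computed by a rank-revealing least-squares solve, which is numerically
   stable for near-collinear candidates.

A subtlety worth knowing: UFS guarantees a *maximal non-collinear set*,
not the identity of the removed columns. If a redundant column is
examined before the columns that generate it, it can enter the selection
and one of its parents is rejected later instead. The information content
is the same, and the number of rejected columns equals the number of
redundant dimensions; the test suite asserts exactly this property rather
than a specific removal list.

Standardization (`fit_standardizer()` / `apply_standardizer()`) always
learns means and standard deviations on training rows only; PLS and ANN
fits are scale-sensitive, and reusing training statistics on test data is
what keeps the split experiments leakage-free.

## Linear models and fit statistics

* `fit_univariate()` is ordinary least squares for
  `log Kd = a + b log Kow` (or log D_ow), reported per charge class and
  for the pooled table. A constant response is reported as slope 0 with
  R² = 0 rather than an error.
* `leverage_filter_refit()` computes the hat-matrix diagonal, flags rows
  with `h_ii > m·p/n` (default multiplier 3 — "high leverage" is rarely
  given a number in applied work, so the conventional 3 is used), removes
  them **once**, and refits. A single pass avoids the poorly determined
  behaviour of iterating removals on small classes.
* `stepwise_regression()` is the classic forward–backward procedure on
  partial t-test p-values with entry/removal thresholds 0.15/0.15 (the
  defaults of the statistical package traditionally used for such
  models). Perfectly collinear candidates get an effective p-value of 1
  and can never enter. Its PRESS-based R²_pred holds the selected
  variable set fixed across leave-one-out folds; this is the common
  package convention and is mildly optimistic, since per-fold
  re-selection would be more honest but is not what reported stepwise
  R²_pred values mean.
* `fit_pls()` is NIPALS PLS1: predictors autoscaled, response centred
  but not scaled (a single response; scaling it would only rescale the
  back-transformed coefficients), X deflated after each component. Each
  x-weight vector's largest-magnitude element is made positive, so
  loadings — and the loading-based descriptor rankings
  (`pls_loading_ranking()`, absolute loadings averaged across models
  before ranking) — are reproducible across runs and sign-stable.
  With as many components as the predictor rank, PLS reproduces the
  least-squares fit; the tests use this identity, and the equivalence of
  the first weight vector with the dominant eigenvector of Xᵀy yᵀX, as
  oracles.
* `select_ncomp_loo()` refits the model n times per candidate component
  count with centring/scaling recomputed inside each fold, and picks the
  count maximising `R²_cv = 1 − PRESS/SST` (smallest count on ties).
* `fit_metrics()` reports `R² = 1 − SSE/SST`,
  `R²_adj = 1 − (1−R²)(n−1)/(n−p−1)`, `R²_pred = 1 − PRESS/SST`
  (which may legitimately be negative), the mean unsigned error, and
  `s = sqrt(SSE/(n−p−1))`. When `n ≤ p + 1` the adjusted statistics are
  undefined and returned as flagged `NA`s with a warning, never silent
  `NaN`s.

## Bayesian neural networks under the evidence framework

The networks are single-hidden-layer perceptrons,
`yhat = b₂ + Σ_j v_j tanh(b₁j + Σ_i w_ij x_i)`, with 2–5 hidden units —
deliberately small for a dataset of a few hundred rows. Training
minimises the regularised error
`M(w) = β E_D + Σ_g α_g E_W(g)`, `E_D = ½Σ(y−yhat)²`,
`E_W(g) = ½Σ_{w∈g} w²`, which is the negative log posterior under a
Gaussian noise model (precision β) and zero-mean Gaussian priors with one
precision α_g per weight group. The ARD grouping assigns one group to
each input's fan-out weights, plus separate groups for the hidden biases,
the hidden→output weights, and the output bias, so bias and output
weights are regularised but never compete with the per-input relevance
parameters.

One outer iteration of `bnn_train()` alternates:

1. **MAP fit** (`bnn_train_map()`): deterministic quasi-Newton (BFGS)
   minimisation of `M(w)` with the exact back-propagated gradient, capped
   at 100 inner iterations. The returned point never has a higher
   objective than the starting point.
2. **Hyperparameter re-estimation** (`bnn_update_hyperparams()`): with
   `A = β JᵀJ + diag(α)` (a Gauss–Newton approximation of the Hessian of
   `M`; see below), the effective number of well-determined parameters
   per group is `γ_g = |g| − α_g tr_g(A⁻¹)`, and the MacKay updates are
   `α_g ← γ_g / 2E_W(g)` and `β ← (N − Σ_g γ_g) / 2E_D`. Since
   `A ⪰ diag(α)`, each `γ_g` naturally lies in `[0, |g|]`; the code
   additionally clamps `α` to `[1e−8, 1e8]` and floors `β` at `1e−8` so a
   perfectly fit group can never produce a division by zero.

Eight outer loops are the default — hyperparameters stabilise well within
that on data of this size. Weight initialisation is Gaussian with
standard deviation `1/sqrt(fan-in)`, seeded per network, and targets are
centred (not scaled) before training with the centre stored on the model.

**Numerical choices.** The data-term Hessian uses the Gauss–Newton form
`JᵀJ` everywhere rather than the exact Hessian: near the saddle points
that tanh networks produce, the exact Hessian is frequently indefinite,
while `JᵀJ` is always positive semidefinite, and at a good fit (small
residuals) the two coincide. Eigenvalues of `A` are floored at `1e−10`
before inversion and log-determinants; floored directions contribute
`γ ≈ 0`, which is the conservative choice (an ill-determined direction is
not evidence of a well-determined parameter). The log evidence is the
Gaussian (Laplace) approximation
`−β E_D − Σ α_g E_W(g) − ½ log det A + ½ Σ |g| log α_g + (N/2) log β − (N/2) log 2π`.

**Linear test mode.** `bnn_architecture(p, n_hidden = 0)` builds a
network with no hidden layer — a plain linear map with per-input ARD
groups. For that architecture the Gauss–Newton Hessian is exact and the
evidence framework coincides, in a single outer iteration, with
closed-form Bayesian ridge regression: MAP weights, γ, the α/β updates
and the (there exact) log marginal likelihood. The test suite exploits
this as an independent oracle, computing the marginal likelihood through
the n×n covariance identity rather than the Laplace expression. The hook
is a testing device, not a modelling option.

**Committees.** `train_committee()` trains `n_networks` replicas
differing only in their initialisation seed and keeps the `k` with the
highest log evidence (ties broken by seed order; defaults 100 and 10,
scaled down where runtime matters). Committee prediction is the
arithmetic mean of member predictions, optionally with the member
min/max spread. `ard_ranking()` ranks inputs within each member by
ascending α (small decay = large admissible weights = relevant), then
orders by mean rank across members with name tie-breaks.

## The experiment layer

`make_splits()` draws independent test sets (default five splits of 60
measurements out of 297, leaving 237 for training) by uniform sampling
without replacement. Splitting at measurement level matches the
arithmetic of published protocols, but lets replicates of one compound
straddle train and test, which leaks compound identity; a
`level = "compound"` option keeps compounds intact at the cost of
slightly variable test sizes (flagged when inexact). The default remains
measurement-level because that is what the reference protocol does.

`run_pls_experiment()` and `run_ann_experiment()` fit the reduction
(CV filter + UFS), the standardizer, component counts and all
hyperparameters on training rows only, per split. A
`global_reduction = TRUE` flag reproduces protocols that fixed the
descriptor set once on the full table (mild leakage, faithful to common
practice). Reports carry per-split rows plus mean/sd rows recomputed on
demand from the split rows, so the aggregate can never drift from its
inputs. The "variance" column is the cumulative fraction of X-variance
captured by the selected components. `train_production_models()` refits
both model families on the full table with the same protocol and labels
the resulting statistics as in-sample fits, not predictive estimates.

## The synthetic-data generator

`generate_dataset()` emulates the structure of a literature K_d
compilation:

* **Margins**: 297 measurements of 148 compounds; charge-class
  measurement counts 92 (uncharged) / 105 (positive) / 76 (negative) /
  24 (zwitterion) over 44/60/28/16 compounds. Replicate counts start at
  one per compound, with the remainder allocated by preferential
  attachment (probability proportional to the current count, capped at
  12), giving the typical "mostly 1–3 measurements, tail up to a dozen"
  mix. The per-compound replicate-count distribution of real
  compilations is not published; only examples and the spread statistic
  are, which this scheme matches.
* **Truth**: per class, `log Kd = a_c + b_c log Kow` with slopes/
  intercepts 0.42/1.07 (uncharged), 0.45/1.53 (positive), 0.0/1.73
  (negative), 0.1/1.5 (zwitterion — given its own small slope because no
  usable univariate model exists for that class in practice), plus a
  per-compound Gaussian deviation (sd 0.2) and an optional smooth
  nonlinearity.
* **Replicate scatter**: uniform measurement noise whose width is
  calibrated from the realised replicate-count mix so the expected mean
  per-compound range equals the 0.91 log-unit target — the range of k
  iid uniforms of width w has expectation `w(k−1)/(k+1)`, which makes
  the calibration closed-form. Setting the target to 0 gives
  replicate-noise-free data.
* **Descriptors** (compound-level, replicated across a compound's
  measurements): an exact copy of log K_ow; three near-binary charge
  surrogates (class indicator + noise, sd 0.05) of the kind real charge
  descriptors provide; two standard-normal signal columns feeding the
  nonlinearity; pure-noise columns; and near-collinear redundant columns
  (linear combinations of 2–3 signal columns plus noise, sd 0.02, with
  the generating combinations recorded in the truth object) that give
  UFS a known correct answer.
* **Nonlinearity**: `amplitude × [cos(1.3(0.8 s₁ + 0.6 s₂)) − c₁ +
  0.35 (tanh(1.2 s₂ − 0.5) + c₂)]` with analytic centring constants. The
  cosine ridge is an even function, so it carries *no* linear signal at
  all; the tanh ridge adds a saturating, partially linear component. Both
  are single-ridge functions a 2-unit tanh network can represent. The
  term deliberately excludes log K_ow, so the class slopes stay exactly
  recoverable by univariate regression whatever the amplitude.
* **log K_ow distribution**: Normal(2.0, 2.6), matching the wide spread
  (about −2 to 8) of pharmaceutical hydrophobicity in such compilations.
  Together with the compound-level scatter this puts the class-wise
  univariate R² around 0.5–0.65 — somewhat crisper than typical
  literature compilations (~0.45–0.5), a deliberate trade-off so that
  parameter-recovery tests at class sizes of 44–60 compounds have
  adequate statistical power. Note that replicate measurements cluster
  within compounds: the precision of a fitted class slope is governed by
  the number of *compounds*, not measurements.

What the generator does **not** emulate: real descriptor marginals or
inter-descriptor chemistry, pH/protomer effects, sludge-type covariates,
or study-level biases. Tests passing on synthetic data therefore
demonstrate that the algorithms are implemented correctly and recover
known structure — not that any particular predictive accuracy will be
achieved on real measurements.

## Determinism and reproducibility

Every stochastic step (generation, splitting, weight initialisation)
draws its seed from a master seed through named substreams, so a full
experiment is bit-reproducible and perturbing test rows provably cannot
change any trained model (asserted by a corruption test). Models
serialize to JSON at full double precision and reproduce their
predictions exactly after reload.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run the study design at its
native size (297 measurements, 5 splits of 237/60) but scale the
committee parameters to 20 networks with the best 5 retained, and the
hidden-layer scan to the headline 2-unit case. These sizes keep the full
pipeline exercise to a couple of minutes while leaving every algorithmic
path identical to the full 100-network protocol; `run_config()` defaults
document the full-scale values.

## Known limitations

* The evidence approximation uses a Gauss–Newton Hessian; log-evidence
  values near very flat or saddle-like optima are approximate, which can
  reorder committee members whose evidences are nearly tied.
* Stepwise R²_pred does not re-select variables per fold (documented
  optimistic convention).
* Measurement-level splitting leaks compound identity between train and
  test; use `level = "compound"` for a stricter protocol.
* ARD relevance is a ranking, not an effect size; correlated inputs
  share relevance in unpredictable proportions.
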