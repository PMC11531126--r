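---
title: "Majority-vote feature selection for high-dimensional survival data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Majority-vote feature selection for high-dimensional survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfsurv)
```

## The problem

In clinical and omics survival studies the number of covariates $p$ often
rivals or exceeds the number of subjects $n$, while only a handful of
covariates actually drive the hazard. Different variable-selection methods
reach sparsity by very different mechanisms — convex penalties, nonconvex
penalties, greedy boosting, tree ensembles — and in practice they disagree on
the margins of their selections. `hfsurv` implements a simple aggregation
rule: run four established selectors and keep only the features on which at
least three of the four agree. The intuition is that a feature retained by a
convex penalty, a bias-reduced nonconvex penalty, a gradient-boosting path
*and/or* a rank-based forest statistic is unlikely to be an artifact of any
one method's bias.

All methods operate on right-censored data $\{(Y_i, \delta_i, X_i)\}$ with
$Y_i = \min(T_i, C_i)$ and $\delta_i = I(T_i \le C_i)$, under the Cox
proportional-hazards model $h(t \mid x) = h_0(t)\exp(x'\beta)$.

## The four base selectors

**LASSO–Cox** minimizes the negative mean log partial likelihood plus
$\lambda \sum_j |\beta_j|$. The partial likelihood uses the Breslow
convention for tied event times everywhere in this package (tied events
share one risk-set denominator); the baseline cumulative hazard is the
matching Breslow estimator, kept as a right-continuous step function with no
interpolation. $\lambda$ is chosen on a 50-point log-spaced grid from the
data-derived $\lambda_{max}$ (the smallest value with an all-zero solution)
down to $0.01\,\lambda_{max}$, by 10-fold cross-validated partial-likelihood
deviance in the Verweij–van Houwelingen form (full-data minus training-part
log partial likelihood at the fold fit) — the partial likelihood does not
decompose over held-out subjects, so a plain per-fold likelihood would be
biased. Folds are stratified on the event indicator and seeded.

**SCAD–Cox** replaces the L1 penalty with the smoothly clipped absolute
deviation penalty, defined through its derivative: flat at $\lambda$ below
$\lambda$, decaying linearly to zero at $a\lambda$, and zero beyond, with
the conventional $a = 3.7$. Large coefficients therefore escape the
shrinkage bias of the lasso. The nonconvex problem is solved by local linear
approximation: iteratively reweighted lasso with weights
$p'_\lambda(|\beta_j^{(k)}|)$, started from the lasso solution and iterated
up to five times (stopping early once the weights stabilize). This avoids a
general nonconvex solver while keeping the fixed points of the SCAD
stationarity conditions.

**Component-wise Cox boosting** starts from $\beta = 0$ and repeats: compute
the negative gradient of the partial likelihood — the martingale residuals
$u_i = \delta_i - \hat H_0(Y_i) e^{X_i'\beta}$ —, fit the univariate
least-squares coefficient $\hat b_j = (X_j'X_j)^{-1} X_j'u$ for every
standardized column, update the single column minimizing the residual sum of
squares by $\nu \hat b_{j^*}$ with step length $\nu = 0.1$. The number of
steps $m_{stop}$ controls selection: it is tuned on a grid $0..200$ by the
same stratified 10-fold Verweij–van Houwelingen deviance, evaluated
incrementally along each fold's boosting path. Selected features are those
with a nonzero boosted coefficient at the chosen $m_{stop}$.

**Random survival forest variable selection** grows bootstrap survival trees
with log-rank splitting: at each node `mtry` randomly drawn features are
searched over all midpoint cut points, maximizing the standardized absolute
log-rank statistic, subject to each child receiving at least one event;
nodes stop splitting below 15 events or 3 distinct event times. Leaf
cumulative hazards are Nelson–Aalen estimates; the ensemble averages them
across trees. A feature's *minimal depth* in a tree is the depth of the
shallowest node split on it (unused features count as that tree's maximum
depth plus one — a finite, rank-preserving penalty; the exact
maximal-subtree depth distribution is deliberately out of scope). With
$p/n < 10$ the selector keeps features whose mean minimal depth lies below
the forest-wide mean. With $p/n \ge 10$ it switches to *variable hunting*:
repeatedly (default 50 times) subsample rows and features, rank by minimal
depth, grow a nested model in that order until the joint out-of-bag
importance (one minus the OOB error of a forest on the model's features)
changes by less than $10^{-3}$ over three consecutive additions, and keep
the features present in at least half of the repetitions. The stabilization
rule and the 50% frequency cutoff are our operationalization of a procedure
that is usually described only loosely; they are configurable in
`rsf_config()`.

## The majority vote

Let $FS_1, \dots, FS_4$ be the four selected sets and $count(f)$ the number
of sets containing feature $f$. The final selection is

$$FS_{final} = \{ f : count(f) \ge 3 \},$$

computed over the *union* of the four sets. (A literal reading that first
intersects all four sets and then filters by $count \ge 3$ is vacuous —
everything in a four-way intersection has count 4 — so the union-with-count
reading is implemented.) The threshold is exposed: threshold 1 gives the
union, 4 the strict intersection, and the rule is monotone in between. If
any base selector fails, the pipeline aborts naming it rather than voting
over three survivors, which would silently change the rule's semantics. An
empty final set is returned as such with a warning; only the benchmark layer
substitutes a documented fallback (the selector's top-ranked single
feature), because predictors need at least one covariate.

## Evaluation metrics

All metrics are computed on a held-out test part and handle censoring
explicitly:

* **IPCW Brier score.** $BS(t)$ averages squared differences between the
  event status at $t$ and $\hat S(t \mid z_i)$, weighting subjects with an
  observed event by $1/\hat G(t_i)$ and subjects still at risk by
  $1/\hat G(t)$, where $\hat G$ is the reverse Kaplan–Meier estimate of the
  censoring distribution on the test set; subjects censored before $t$
  contribute nothing. The integrated score divides the trapezoidal integral
  over $[0, \max t_i]$ by $\max t_i$; the grid is zero plus the distinct
  test-set event times (including $t = 0$ makes the normalization exact:
  a constant $BS \equiv c$ integrates to exactly $c$).
* **C-index.** A pair ordered by time is comparable iff the earlier subject
  experienced the event; at tied times exactly one member must be an event.
  This rule reproduces the canonical 10-pair/6-pair five-subject worked
  example. Tied predictions count one half, which makes random scores sit at
  exactly 0.5 in expectation. Hazard mode compares risk scores ($X\hat\beta$
  for Cox, ensemble mortality for forests); survival mode compares predicted
  curves at the median observed event time, a fixed reference that makes the
  statistic well defined for curve-valued predictors.
* **IAE / ISE.** The cohort-average predicted curve is compared to the
  test-set Kaplan–Meier estimate by trapezoidal integration of the absolute
  and squared differences over $[0, \max t_i]$. The marginal (cohort-level)
  comparison is deliberate: KM is a marginal estimator, and comparing
  per-subject curves to it would conflate discrimination with calibration.
  Values are in time units and unnormalized, so they are comparable across
  selectors on one dataset but not across datasets.

## The synthetic-data generator

Real benchmark collections in this area (breast-cancer cohorts,
gene-expression panels, registry data) are not redistributable, so the
package ships a generator that emulates their structure: $n$ between tens
and hundreds, $p$ from tens to thousands, a sparse linear predictor, and
substantial right-censoring.

* Covariates are multivariate normal with exchangeable correlation
  (default 0.2): $x_j = \sqrt\rho\, z_0 + \sqrt{1-\rho}\, z_j$. The default
  mimics mild co-expression without dominating selection.
* Event times follow a Weibull proportional-hazards model,
  $H_0(t) = (t/b)^k$ with shape $k = 1.5$ and scale $b = 1$ by default —
  an increasing hazard typical of progression/relapse endpoints; the Cox
  methods never see or use this parametric form.
* True coefficients put `n_informative` entries of magnitude
  `beta_magnitude` with alternating signs on the first covariates; the
  generator returns them for support-recovery experiments.
* Censoring is independent exponential; its rate is calibrated by
  root-finding on the drawn event-time sample so the expected censoring
  fraction equals `censor_rate` exactly in expectation. Monte-Carlo checks
  over 50 seeds keep the realized fraction within a few points of the
  target.

What a green recovery test establishes is therefore: under proportional
hazards, independent censoring, equicorrelated Gaussian covariates and a
sparse linear signal, the selectors find the planted support and the
majority vote does not inflate the false-discovery proportion. It does not
establish robustness to non-proportional hazards, informative censoring,
heavy-tailed covariates or time-varying effects — none of which the
generator produces.

## Numerical choices

* **Penalized solver.** The textbook recipe for this family of solvers is
  cyclic coordinate descent with soft-thresholding on a quadratic
  approximation of the partial likelihood. With only the diagonal of the eta-space Hessian,
  that iteration converges linearly at a rate we measured around 0.7 —
  dozens of outer cycles per fit. For $p \le 500$ the package therefore
  assembles the exact full Hessian of the mean log partial likelihood in
  $O(np + Kp^2)$ ($K$ = distinct event times) and performs guarded
  proximal-Newton steps: coordinate descent with soft-thresholding on the
  exact quadratic model, then a monotone line search on the true penalized
  objective (halve on increase, expand while decreasing). Solutions agree
  with the unpenalized Newton fit to $10^{-8}$ at $\lambda = 0$ and with
  glmnet along the path to within coefficient tolerance $0.05$. Above
  $p = 500$ the diagonal surrogate with the same line search is used.
* **Convergence.** Newton Cox fitter: relative objective change
  $< 10^{-9}$ or gradient max-norm $< 10^{-6}$, at most 100 iterations;
  monotone-likelihood (separation) flagged when a coefficient magnitude
  passes 50. Penalized solver: relative objective change $< 10^{-9}$ and
  maximum coefficient move $< 10^{-5}$.
* **Sparsity.** A coefficient is "selected" when its standardized magnitude
  is at least `zero_tol` $= 10^{-8}$ — an explicit, testable definition.
* **Overflow safety.** Linear predictors are centered by their maximum
  before exponentiation everywhere.
* **Ties.** Breslow everywhere (likelihood, baseline, residuals); split
  statistics use the variance-corrected hypergeometric form with the
  $(Y-d)/(Y-1)$ factor, skipping risk sets of size one.
* **Tie-breaks.** Boosting breaks equal least-squares improvements by the
  lowest column index (deterministic); forest split-score ties are broken
  uniformly at random from the forest's seed stream.
* **Degenerate inputs.** Constant covariate columns are skipped (boosting,
  splitting) or absorbed (penalties, scale set to 1 with a zero
  coefficient); datasets must contain at least one event and two subjects;
  folds are redrawn (up to 10 times) if any training part lacks events.

## Benchmarking protocol

The source studies report single metric values per dataset without stating
a split protocol. The harness defaults are therefore explicit stand-ins:
stratified 70/30 train/test splits on the event indicator, 10 repeated
splits averaged per cell, selection always inside the training part. Win
counts per selector (minimum IBS/IAE, maximum C-index per dataset, ties
split) reproduce the "how often is each selector best" comparison. Repeats
are averaged before datasets so unbalanced repeat counts cannot tilt the
dataset average.

## Known limitations

* No left truncation, interval censoring, competing risks or time-varying
  covariates.
* Efron tie handling, stratified Cox and robust variances are out of scope.
* The variable-hunting branch is an operationalization of an
  under-specified procedure and should be read as such.
* IAE/ISE depend on the dataset's time unit; compare them only within a
  dataset.
* The neural-network discrete-time predictor that sometimes accompanies
  this benchmarking style is intentionally not implemented: no
  reproducible architecture or loss hyperparameters are available.
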