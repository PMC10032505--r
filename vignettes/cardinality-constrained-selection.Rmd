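---
title: "Exact L0 feature selection by DC penalty: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact L0 feature selection by DC penalty: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardsel)
```

## The problem

Prognostic models built from clinical laboratory data must balance
predictive accuracy against the cost and complexity of deployment: each
additional marker is an additional assay, and assays come bundled in
priced kits.  `cardsel` fits Cox proportional hazards (and logistic or
linear) models under a *hard* cardinality constraint
$\lVert\beta\rVert_0 \le K$, i.e. best-subset selection, rather than the
soft shrinkage of L1/L2 penalties.  Coefficients of selected features are
not shrunk toward zero — a feature is either in the model at its fitted
effect size or out — which is why cardinality-constrained paths tend to
saturate quickly and behave more like forward selection than like the
lasso.

## Exact reformulation and the DC penalty

The constraint is combinatorial and discontinuous.  We use its exact
continuous rewriting via the largest-K norm
$|||\beta|||_{[K]} = \sum_{i=1}^{K} |\beta_{(i)}|$ (sum of the K largest
absolute values, a proper convex norm):

$$\lVert\beta\rVert_0 \le K
  \iff \lVert\beta\rVert_1 - |||\beta|||_{[K]} = 0 .$$

Penalizing the (nonnegative) constraint residual gives the unconstrained
problem

$$\min_\beta\; f(\beta)
  = \underbrace{-l(\beta) + \rho\lVert\beta\rVert_1}_{f_1}
  - \underbrace{\rho\,|||\beta|||_{[K]}}_{f_2},$$

a difference of two convex functions.  No approximation of the L0
pseudonorm is involved: for sufficiently large $\rho$ the minimizers are
feasible for the original constraint, and the feasible sets coincide
exactly.

**Kit grouping.**  When features come in measurement kits, the cardinality
of interest is the number of *kits* used.  We aggregate within-kit
magnitude as $v_g = \sum_{j \in g} |\beta_j|$ and penalize
$\rho(\sum_g v_g - |||v|||_{[K]})$, which is zero precisely when at most
$K$ kits carry nonzero coefficients and reduces to the per-feature penalty
under singleton kits.  Any support-monotone within-kit norm would do; the
L1 sum keeps $\sum_g v_g = \lVert\beta\rVert_1$, so $f_1$ is unchanged and
the DC structure stays exact.  (The magnitude-based aggregation is our
design choice; an indicator-based variant would give the same feasible
set but a nonconvex $f_2$.)

## The solver

The two bundle methods used in the original Fortran implementation of
this methodology are deliberately not reproduced; the approach does not
depend on the specific nonsmooth optimizer.  We use a DCA-style outer
loop: at the current iterate, replace $f_2$ by its affine minorant
$f_2(\beta^t) + g^\top(\beta - \beta^t)$ with
$g \in \partial f_2(\beta^t)$, and minimize the convex surrogate
$-l(\beta) + \rho\lVert\beta\rVert_1 - g^\top\beta$ with accelerated
proximal gradient (FISTA): backtracking line search, soft-thresholding
prox (hence exact zeros), momentum restart on objective increase, and
return of the best iterate.  Since the surrogate majorizes $f$ at the
expansion point, each accepted outer step decreases $f$; the solver aborts
with a diagnostic if it ever observes an increase beyond float noise.

**Subgradient choice.**  On the chosen top-K index set the subgradient of
$|\cdot|$ at a *nonzero* coordinate is its sign; at an exactly zero
coordinate any value in $[-1, 1]$ is valid.  The exported
`f2_subgradient` returns 0 there (deterministic, ties toward the lowest
index).  Inside the solver we instead pick
$\mathrm{sign}(-\partial_j \text{loss})$ for zero coordinates in the
chosen set: still a valid subgradient, but it un-shrinks the most
promising coordinate and removes a spurious fixed point of the iteration
at the origin (visible in the one-dimensional problem $(\beta-2)^2$,
$K=1$, where the 0 choice would freeze $\beta = 0$).

**Penalty escalation.**  $\rho$ is searched on the geometric grid
$\rho_0 m^t$ (defaults $\rho_0 = 1$, $m = 5$, cap $10^6$), each solve
restarted from the *original* starting point rather than warm-started:
with a too-small $\rho$ the solution goes dense and would wash out the
information carried by the start.  A solution with $\lVert\hat\beta\rVert_0
\le K$ is accepted immediately — a stricter "exactly $= K$" rule can never
be repaired by increasing $\rho$ further, since larger $\rho$ only prunes.
If the grid is exhausted the result is returned flagged `converged =
FALSE`; callers (the path algorithm) drop such candidates.

## The incremental path

Stage 0 computes the unregularized optimum $\bar\beta$ (BFGS on the smooth
convex loss).  Stage $i$ builds up to $p$ starting points: candidate $j$
equals the stage $i-1$ solution with coordinate $j$ (all coordinates of
kit $j$ in grouped mode) replaced by $\bar\beta_j$, and candidates whose
support does not exceed $i-1$ are dropped.  Each start is solved through
the escalation loop; the converged candidate with the smallest
*unpenalized* loss wins.  Two deliberate details:

* **Monotonicity guard.**  The stage $i-1$ solution is feasible for
  $K = i$ and is added to the stage-$i$ comparison, so the loss sequence
  along the path is non-increasing by construction.  This costs one loss
  evaluation per stage and goes beyond the literal candidate set of the
  incremental algorithm, which compares only the stage-$i$ candidates.
* **Determinism.**  Candidate solves are independent (and could run
  concurrently) but are reduced in candidate-index order with strict
  `which.min` tie-breaking, so repeated runs are bit-identical.

For high-dimensional problems ($p \ge 100$, or whenever `gamma < 1` is
set) a screening heuristic scores each candidate by a one-dimensional
line search of the loss from the previous solution toward the candidate
and keeps the best $\lceil\gamma m\rceil$ of $m$ candidates;
$\gamma = 1$ recovers the full multi-start exactly.  This reconstruction
is behavior-compatible with the published acceleration (same inputs, same
$\gamma = 1$ limit) but is not guaranteed identical to it, as its exact
one-dimensional subproblem is not specified in the available text.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `rho_initial`, `rho_multiplier`, `rho_max` | 1, 5, 1e6 | geometric penalty grid; escalation stops at the first feasible support |
| `zero_tol` | 1e-6 | support threshold on standardized coefficients; the prox yields exact zeros, this is a guard |
| `inner_tol`, `inner_max_iters` | 1e-7, 500 | FISTA stop (max-norm step) and cap |
| `outer_tol`, `max_outer_iters` | 1e-9, 50 | DCA relative-decrease stop and cap |
| `gamma` | 1 | start-screening fraction; engaged automatically at $p \ge 100$ |
| `standardize` | TRUE | z-score features before fitting, invert on report; matches common practice for mixed-unit clinical panels.  Standardization is a reparameterization for the Cox loss but changes which supports the penalty favors, since $\rho$ treats all coordinates equally |

The logistic and gaussian families carry an unpenalized intercept that
never counts toward cardinality; the Cox partial likelihood has none.
Ties in survival times use Breslow's approximation only (no Efron
option).  Harrell's C counts prediction ties as 1/2 and treats pairs with
equal times as non-comparable — the convention is stated here because
published analyses often leave it implicit.

## What the synthetic generator does (and does not) emulate

`simulate_cox_data` draws standard-normal features with exchangeable
pairwise correlation, exponential event times with rate
$\exp(x^\top\beta_{\mathrm{true}})$ times a baseline, and independent
exponential censoring whose rate is calibrated by bisection so the
realized censoring fraction matches the target (default 0.3, typical of
advanced-cancer registry cohorts).  All randomness flows from the single
seed in the spec; the caller's RNG state is untouched.

It does **not** emulate: missingness and imputation artifacts, feature
blocks with heterogeneous scales or heavy tails, informative censoring,
non-proportional hazards, or the arbitrary correlation structure of real
laboratory panels.  A green test on this generator therefore establishes
correctness of the optimization and evaluation machinery under the stated
model — not clinical validity of selected markers on any real cohort.

## Numerical choices and degenerate inputs

* Log-sum-exp terms use max-subtraction; a non-finite loss raises an
  error rather than propagating NaN.
* Risk-set sums are prefix sums over rows sorted by descending follow-up,
  giving $O(np)$ loss/gradient evaluations including tied failure times.
* Cross-validation folds are stratified on the event indicator (class
  label for logistic); a fold on which the metric is undefined triggers a
  re-randomized fold assignment, with an error after five attempts.
  Leave-one-out CV is consequently unsupported for these rank metrics: a
  singleton test fold has no comparable pair and no second class.
* Bootstrap resamples without events are redrawn against a budget of 5B.
* `pareto_front` keeps points tied on both coordinates; the front is
  unique and order-invariant.

## Known limitations

The solver is a local method: multi-start mitigates but does not remove
the possibility of missing the global best subset (the exhaustive-oracle
acceptance check requires agreement in at least 80% of seeded replicates,
not all).  Costs enter evaluation only, not the objective; cost-aware
fitting would be a harder discrete problem.  Baseline-hazard estimation
and absolute survival curves are out of scope, as are comparator
re-implementations (lasso/SCAD-type shrinkage); external models can be
placed on the same Pareto plot via `pareto_front` on their (cost,
accuracy) pairs.
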