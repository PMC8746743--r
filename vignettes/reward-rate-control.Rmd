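---
title: "Reward-rate-optimal control allocation: model, inversion, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-rate-optimal control allocation: model, inversion, and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmrr)
```

## The model

When people can choose how hard to work on a speeded task, two distinct
control levers are available to them within the drift diffusion model
(DDM) of choice: the rate of evidence accumulation (drift rate $v$,
reflecting attentional intensity) and the amount of evidence required
before responding (boundary separation, or threshold, $a$, reflecting
caution). This package implements a normative account of how monetary
incentives should shape the joint setting of these two levers, and the
inverse problem of reading a person's subjective incentive weights back
off their behavior.

For the unbiased two-boundary diffusion (start point $a/2$, diffusion
coefficient $\sigma$), expected error rate and mean decision time have
closed forms:

$$ER = \frac{1}{1 + e^{a v / \sigma^2}}, \qquad
DT = \frac{a}{2v}\tanh\!\left(\frac{a v}{2\sigma^2}\right),$$

with the removable singularity at $v = 0$ handled by its analytic limits
($ER = 1/2$, $DT = a^2/4\sigma^2$). A decision maker who earns a
subjective reward $R$ per correct response and loses a subjective penalty
$P$ per error, and who pays an effort cost for sustaining drift, is
assumed to maximize the effort-discounted reward rate

$$RR(v, a) = \frac{R\,(1 - ER) - P \cdot ER}{DT + NDT} - E\,v^2,$$

where $NDT$ is non-decision time and $E$ the effort-cost weight. Three
assumptions are doing the work here: (1) the decision maker controls
exactly these two levers; (2) they jointly maximize reward rate; (3)
drift is costly, with a nonlinear (by default quadratic) cost. The cost
term is not decoration — without it the objective grows without bound in
$v$ and the "optimal" strategy is an arbitrarily fast, perfectly accurate
response. With it, the optimum is interior and moves in characteristic
ways: more reward pulls drift up (and threshold slightly down), more
penalty pushes the threshold up. Because the optimum depends on
incentives only through $R/E$ and $P/E$, $E$ is normalized to 1 and $R$,
$P$ are expressed in units of effort cost.

```{r}
pol <- optimize_policy(incentive_weights(10, 10), ndt = 0.4)
pol
```

### Cost forms

`cost_spec()` supports `quadratic` ($E v^2$, the default), `linear`
($E |v|$), `exponential`, and `none`. The exponential family is
parameterized as $E(e^{v} - 1)$ so the cost vanishes at $v = 0$; the
offset is our choice — only the family, not the exact formula, is fixed
by prior work, and the subtraction keeps the three forms comparable at
zero drift. All three costed forms make qualitatively identical
predictions for the incentive effects (see `compare_cost_forms()`); the
quadratic form yields the smoothest objective and is the default. Only
drift carries an effort cost: the threshold already pays an implicit
price through the speed–accuracy tradeoff, so a separate threshold cost
is not needed for any of the qualitative predictions. A hook
(`threshold_weight`) exists for a quadratic threshold cost and defaults
to zero.

## Finding the optimum

`optimize_policy()` is deterministic and has no random restarts: a
64 × 64 log-spaced grid over the search box (defaults
$v \in [10^{-3}, 50]$, $a \in [10^{-2}, 20]$, in $\sigma$ units) locates
the basin; L-BFGS-B on $(\log v, \log a)$ with the analytic gradient
refines it; a final damped Newton polish (2 × 2 Hessian by finite
differences of the analytic gradient) drives the gradient below
$10^{-12}$. The result is verified in two independent ways before being
declared converged: the scaled gradient max-norm must be below $10^{-5}$,
and the value must beat every cell of a 200 × 200 grid over the box. The
landscape is smooth and single-peaked over the plotted incentive ranges,
but that is checked against the grid rather than assumed. An optimum
pinned to the box boundary is returned with `converged = FALSE`, never
silently.

One genuine boundary case deserves emphasis: for sufficiently small
reward relative to the effort cost (roughly $R \lesssim 4$ with $E = 1$,
depending on $P$ and $NDT$), the reward rate is negative everywhere and
its supremum (zero) is approached only as $a \to \infty$ with $v \to 0$.
No interior optimum exists — the model predicts disengagement rather than
a finite control configuration. The optimizer reports this honestly as a
boundary hit, and the inversion identity discussed next is only
meaningful in the engaged regime.

## Inverting the model

Given estimated DDM parameters $(\hat v, \hat a)$ for a condition, the
package asks: which incentive weights would make that configuration
optimal? Setting both partial derivatives of $RR$ to zero gives two
stationarity conditions. Because $ER$ and $DT$ do not depend on $(R, P)$,
both conditions are affine in $(R, P)$, so with the quadratic drift cost
the inversion is an exact 2 × 2 linear solve — no optimization, no
starting values, no local minima. `invert_sensitivities()` performs the
solve, reports the condition number of the system and the residual
gradient at the solution, raises a classed error when the geometry is
degenerate (nearly collinear conditions), and flags — rather than clips —
negative recovered weights. The linear route is verified in the test
suite against an independent nonlinear root-finder on the same
stationarity equations.

```{r}
est <- invert_sensitivities(ddm_params(pol$v_star, pol$a_star, ndt = 0.4))
c(reward = est$reward, penalty = est$penalty)
```

Composing the two operations is the package's core correctness property:
`invert_sensitivities(optimize_policy(R, P))` returns $(R, P)$ to
machine precision across the engaged regime.

## Estimating the DDM from trials

`estimate_ddm()` is a deliberately desk-scale, deterministic estimator:
closed-form moment inversion from accuracy and the mean and variance of
correct RTs (the EZ-diffusion scheme), with $\sigma$ fixed at 1,
optionally refined by maximizing the Wiener first-passage likelihood
(`method = "ml"`; the series density is evaluated in compiled code with
the standard small-time/large-time switch). The moment step supplies the
starting point; the likelihood step brings the estimator to the
statistical efficiency frontier, which matters for the recovery study
below. Hierarchical Bayesian fitting is intentionally out of scope.

Accuracies of exactly 0, 1, or 1/2 make the moment inversion undefined
(the log-odds of a correct response carries the drift signal); these
raise a classed condition with an explicit edge-case code instead of
returning a number.

## Simulating trials

`simulate_trials()` draws first-passage times by Euler–Maruyama with a
1 ms default step — plus a within-step Brownian-bridge crossing test:
conditional on a step's endpoints lying inside the boundaries, the
probability that the continuous path touched a boundary in between is
$\exp(-2(b - x_0)(b - x_1)/\sigma^2 \Delta t)$. Plain Euler systematically
overshoots boundaries, biasing first-passage probabilities by an amount
(equivalent to a boundary shift of about $0.58\,\sigma\sqrt{\Delta t}$)
that is *larger* than the Monte-Carlo standard error at $10^5$ paths; the
bridge correction removes this leading-order bias, which is what lets the
closed forms and the sampler agree within 3 SE in the validation suite.
The residual step-discretization effect on decision times is below half a
millisecond. The RNG is R's own stream, so every draw is reproducible
under `set.seed()` or an explicit `seed` argument.

## The synthetic task

`generate_experiment()` emulates a self-paced, interval-based
incentivized Stroop task: fixed intervals drawn uniformly from 8–12 s; as
many trials as fit, each starting immediately after the previous
response; congruent/incongruent mixed 1:1 via i.i.d. assignment (so the
realized proportion varies slightly across intervals); cued
reward-per-correct and penalty-per-error levels — 2 × 2 over {1, 10}
cents with 20 intervals per condition, or 3 × 3 over {1, 5, 10} cents
with 8 intervals per condition. Earnings accounting is exact: each
correct response adds the reward level, each error subtracts the penalty
level, and interval records track correct responses per second and
cumulative earnings.

Choices the task description leaves open, and how we made them:

* **The trial in flight at interval end.** Its handling is not specified
  by the task structure; both options are implemented (`discard`, the
  default, drops it; `truncate` records it as an earnings-neutral
  omission with censored RT) and neither is asserted as canonical.
* **Subjective weights for cued cents.** The generator's ground-truth
  profiles come from `default_incentive_map()`: reward weight rises
  log-linearly from 8 (1¢) to 20 (10¢) — the span over which the
  normative predictions are tabulated — and penalty weight is $5\times$
  the cent amount (5 to 50), encoding the steeper subjective weighting of
  losses while keeping every condition's optimal error rate high enough
  that condition-wise estimation from a realistic session remains
  well-posed.
* **Congruence offsets.** Incongruent trials get a drift decrement
  (default $-0.3$) and threshold increment (default $+0.1$) on top of the
  condition optimum, the characteristic Stroop pattern; offsets violating
  the direction constraints are rejected.
* **Blocks and counterbalancing** are recorded as metadata only: none of
  the analyses implemented here model order effects.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: between-subject heterogeneity in
weights or non-decision time (all simulated subjects share a profile
unless given distinct ones), learning and sequential adjustment across
trials or intervals, RT contamination and lapses, across-trial parameter
variability (no $s_v$, $s_z$, $s_t$), and any incentive-by-congruence
interaction beyond the additive offsets (one can be induced by supplying
per-condition offsets, but it is not the default).

## The recovery study

`run_recovery()` validates the whole loop. For each cell of a weight
grid: optimize $(v, a)$, optionally simulate $n$ trials and re-estimate,
then invert back to $(\hat R, \hat P)$, and correlate recovered with true
weights across the grid. Two regimes: `noiseless` (invert the exact
optimum — an identity up to solver tolerance, the structural sanity
check) and `fitted` (estimation noise from finite data propagates into
the weights — the realistic check).

Defaults, fixed once and used by the acceptance script: a 5 × 5
log-spaced grid with reward weights spanning 8–20 and penalty weights
5–150, $n = 2000$ trials per cell, quadratic cost, $NDT = 0.4$ s,
likelihood-refined estimation. The reward span is the range over which
the normative predictions are tabulated. The penalty span starts at the
same place but is capped at 150 rather than extending to the hundreds:
by 625 the optimal policy's error rate drops to $\sim 10^{-3}$, i.e. two
to four expected errors in 2000 trials, where the error rate is
essentially unidentified and the estimator's preconditions begin to fail;
the cap keeps every cell at roughly ten or more expected errors. Wider
spans can be requested explicitly.

With these settings the recovered-weight correlations are high but
asymmetric — reward recovery is near-perfect while penalty recovery is
noticeably noisier. The asymmetry has a clean origin: the penalty weight
is identified mainly through the error rate, and high-penalty cells are
exactly the ones with the fewest errors to learn from. Both correlations
are themselves stochastic quantities (fresh trial noise each run), so the
validation suite asserts their average over ten replicate simulations;
single runs scatter by a few thousandths (reward) to a few hundredths
(penalty) around that average.

## Numerical choices, in one place

* $\sigma = 1$ by convention; it is a scale, not a parameter, and the
  task description never pins it down. All $v$, $a$ values are in
  $\sigma$ units.
* Drift magnitudes below $10^{-6}$ use the analytic $v \to 0$ limits of
  $ER$, $DT$, and their partials (removable $0/0$).
* The linear cost is non-differentiable at $v = 0$; gradient evaluation
  there raises an explicit error (the optimizer's search space is
  $v > 0$, so the kink never binds in practice).
* Inversion declares the stationarity system degenerate above a condition
  number of $10^{10}$.
* Default search bounds $v \in [10^{-3}, 50]$, $a \in [10^{-2}, 20]$
  cover the entire incentive range tabulated here with an order of
  magnitude to spare; tests probing extreme penalty/reward ratios widen
  the $a$ bound instead of trusting extrapolation.
* Seed fan-out: one master seed expands into per-subject and per-stage
  child seeds via a fixed draw (`derive_seeds()`), so any stage can be
  re-run in isolation and a pipeline run is byte-reproducible from its
  config and seed.

## Problem sizes in the validation suite

The shipped tests use sizes chosen to make sampling error negligible
relative to the tolerances they assert: $10^5$ paths per grid point for
the closed-form/Monte-Carlo agreement checks, $10^5$ trials for the
large-sample estimator recovery, $n \in \{10^3, 10^5\}$ for the
error-shrinkage property, 2000 trials per cell and ten replicates for
the recovery correlations, and six simulated subjects under the
two-level design for the end-to-end behavioral pattern checks.

## Known limitations

The estimator is deliberately non-hierarchical, so per-subject estimates
need a few hundred trials per condition to be stable; the inversion is
exact only under the quadratic cost (other costs would need a nonlinear
solve); the normative model is congruence-free (congruence lives in the
generator and the estimator's data, not in the objective); and the
recovery correlations quoted anywhere in this package refer to the
synthetic conditions described above, not to any human dataset.
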