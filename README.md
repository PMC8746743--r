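# ddmrr — reward-rate-optimal control allocation in the drift diffusion model

`ddmrr` is an R package for computational cognitive scientists studying
how performance incentives shape cognitive control. It implements a
normative model in which a decision maker tunes two drift-diffusion-model
(DDM) parameters — drift rate *v* (attentional intensity) and boundary
separation *a* (response caution) — to maximize an effort-discounted
reward rate, together with the inverse problem: recovering a person's
subjective reward and penalty sensitivities from their estimated DDM
parameters. A synthetic generator of an interval-based, self-paced
incentivized Stroop task makes the entire analysis chain testable without
human data.

## The model

For the unbiased two-boundary diffusion (start *a*/2, noise σ):

    ER = 1 / (1 + exp(a·v/σ²))
    DT = (a / 2v) · tanh(a·v / 2σ²)         (v → 0: DT = a²/4σ²)

A decision maker earning subjective reward *R* per correct response and
losing subjective penalty *P* per error maximizes

    RR(v, a) = [R·(1 − ER) − P·ER] / (DT + NDT) − E·v²

where *NDT* is non-decision time and *E·v²* the effort cost of sustaining
drift (*E* = 1 by normalization: *R* and *P* are in effort-cost units).
The optimum moves in characteristic, dissociable directions: more reward
raises the optimal drift rate (and slightly lowers the threshold); more
penalty raises the optimal threshold. Setting both partial derivatives of
*RR* to zero at estimated parameters (v̂, â) gives two conditions that are
affine in (*R*, *P*), so inferring the sensitivities (R̂, P̂) that make
observed behavior optimal is an exact 2 × 2 linear solve.

## Worked example

Optimal control configuration for symmetric incentives, and its exact
inversion:

```r
library(ddmrr)

pol <- optimize_policy(incentive_weights(10, 10), ndt = 0.4)
pol
#> Optimal control policy: v* = 2.1041, a* = 1.0428, RR* = 8.9391 (converged)

invert_sensitivities(ddm_params(pol$v_star, pol$a_star, ndt = 0.4))
#> Recovered sensitivities: R-hat = 10, P-hat = 10
```

Normative predictions across a 2 × 2 incentive grid — drift rate rises
with reward, threshold rises with penalty (and dips slightly with
reward):

```r
prediction_grid(reward_levels = c(8, 20), penalty_levels = c(5, 50))
#>   reward penalty v_star a_star rr_star converged
#> 1      8       5  1.741 0.9063   7.080      TRUE
#> 2     20       5  2.602 0.7235  26.472      TRUE
#> 3      8      50  2.078 1.9109   3.901      TRUE
#> 4     20      50  3.098 1.1537  21.808      TRUE
```

The full synthetic pipeline — simulate the interval-based Stroop task
from reward-rate-optimal profiles, estimate condition-wise DDM
parameters, and invert them into sensitivities:

```r
bundle <- run_full_pipeline(run_config(study = 1, n_subjects = 4, seed = 7))
bundle$ddm_estimates
#>   condition_reward condition_penalty v_hat a_hat    n accuracy
#> 1                1                 1  1.56 0.980 1316    0.821
#> 2                1                10  1.97 1.935  877    0.978
#> 3               10                 1  2.46 0.777 1507    0.871
#> 4               10                10  2.90 1.214 1281    0.971
bundle$sensitivities[, c("condition_reward", "condition_penalty",
                         "reward_hat", "penalty_hat")]
#>   condition_reward condition_penalty reward_hat penalty_hat
#> 1                1                 1       6.24        4.74
#> 2                1                10       7.33       41.59
#> 3               10                 1      16.74        6.27
#> 4               10                10      16.75       44.35
```

The estimated drift rate is higher in high-reward conditions (2.46–2.90
vs 1.56–1.97) and the estimated threshold higher in high-penalty
conditions (1.214–1.935 vs 0.777–0.980); the recovered sensitivities
track the cued incentive levels on both axes. A parameter-recovery study
quantifies this across a grid of ground-truth weights:

```r
run_recovery(seed = 5)
#> Sensitivity recovery (fitted regime, 2000 trials/cell): 25/25 cells ok; r(R) = 0.991, r(P) = 0.961
```

A thin command-line wrapper over the same functions lives at
`inst/cli/ddmrr.R` (`optimize`, `grid`, `invert`, `recover`, `simulate`
subcommands).

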