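---
title: "The speed–effort–accuracy trade-off: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The speed–effort–accuracy trade-off: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprteffort)
```

## The decision problem

An agent faces a binary classification: is the state of the world good
or bad (a fruiting tree worth climbing, a patch worth foraging)? It
gathers a stream of binary samples whose distribution depends on the
state — a sample reads 1 with probability `eps_good` under the good
state and `eps_bad < eps_good` under the bad one — and applies the
sequential probability ratio test (SPRT), the optimal sequential test
between two simple hypotheses. Each perceived sample adds a
log-likelihood weight to a running decision variable, and the agent
commits to whichever hypothesis's boundary the variable reaches first.
The threshold parameter `theta` in (0.5, 1) sets symmetric stopping
boundaries at `±log(theta/(1 - theta))`: the nearer `theta` is to 1, the
more evidence is demanded and the slower but more accurate the decision.

What makes this package's model distinctive is that perception itself is
costly and imperfect. With effort level `phi` a sample is read correctly
with probability `phi`; otherwise the reading is a fair coin flip.
Effort therefore tunes the *quality* of each unit of evidence. The agent
knows its own error rate, so it weights evidence by the effective
("adjusted") probabilities

```
eps'_g = phi * eps_good + (1 - phi) / 2
eps'_b = phi * eps_bad  + (1 - phi) / 2
```

rather than the raw ones. At `phi = 0` the two effective distributions
coincide at 1/2, the weights vanish, and no decision is ever reached —
the uninformative limit.

## Costs, benefits and fitness

Every sample costs `c_time + c_effort`: a baseline cost of time
(predation risk, opportunity cost — set by the environment) plus the
price of the chosen effort level. Effort shows diminishing returns: we
use the hyperbolic saturating curve `phi = c_effort / (k + c_effort)`,
whose exact inverse `c_effort = k * phi / (1 - phi)` diverges as
`phi -> 1`. The constant `k` is the half-saturation point: spending `k`
per sample removes half the perceptual error. Because perfect perception
is unaffordable, effort grids stop at `phi = 0.98`.

A correct decision earns a benefit `B`; the fitness of a strategy
`(theta, phi)` is

```
W = B * P_C - (c_time + c_effort) * DT
```

with `P_C` the proportion of correct decisions and `DT` the mean number
of samples used. `fitness_value()` implements exactly this.

## Exact solvers: the bounded-walk oracles

Conditional on the true state, the decision variable is a random walk
with steps `w_plus` (probability `eps'` for that state) and `w_minus`,
absorbed at the two boundaries. Two solvers compute `P_C` and `DT`
without simulation:

* **Gambler's-ruin closed form** (`ruin_closed_form()`). In a symmetric
  environment (`eps_bad = 1 - eps_good`) the steps are mirror images and
  the walk lives on a one-dimensional lattice. Its first boundary
  crossing happens exactly `a = ceiling(threshold / w_plus)` steps from
  the origin — no overshoot is possible on a lattice — so textbook ruin
  formulas give the absorption probability `1 / (1 + r^a)` with
  `r = (1 - p)/p` and the expected duration in closed form (`a^2` when
  unbiased). The exported function keeps the strict contract (integer-
  aligned boundaries); the internal dispatcher `oracle_summary()` applies
  the ceiling form for any symmetric cell.

* **Dynamic programming** (`dp_absorption()`). Asymmetric environments
  produce two-step walks with overshoot. Probability mass is propagated
  forward over states indexed by the *number of up-steps taken* — never
  by the rounded decision-variable value, which would risk floating-point
  state collisions — removing absorbed mass each step. Unabsorbed mass
  after `t_max` steps is reported explicitly, and the solver also returns
  the second moment of the absorption time so that simulation checks can
  use exact standard errors.

The walk for the bad state is mirrored (steps and probabilities flipped)
so that upper absorption always means "correct"; `oracle_summary()`
weights the two conditional walks by the prior.

## Numerical choices

* **Boundary slack.** The stopping comparisons in `decide()`, the
  simulation engine and both oracles share a relative tolerance of 1e-9:
  a decision variable that lands *numerically on* a boundary counts as
  crossing it. This matters because boundary-aligned walks are not an
  edge case here: whenever `theta` equals an effective evidence
  probability (e.g. `theta = 0.65` with `phi = 0.6` under the default
  environment), the threshold equals one step exactly, and accumulated
  rounding would otherwise make the simulator absorb on one side of the
  walk but not the other. Genuine gaps between lattice values and
  boundaries are many orders of magnitude larger than the slack.
* **Truncation.** Trials are capped at `t_max` samples (default 10^4).
  Undecided trials are excluded from `p_correct`'s numerator and
  denominator but contribute `t_max` samples to `mean_dt`; both counts
  are reported. Any landscape cell with truncated trials (simulate mode)
  or unabsorbed mass above 1e-9 (oracle mode) is marked invalid and
  excluded from optimisation rather than silently averaged — in
  particular the whole `phi = 0` column.
* **Ties.** In oracle mode, fitness is piecewise constant in `theta`
  within one lattice band (all thresholds needing the same number of
  steps `a` give identical dynamics), so exact ties are routine.
  `find_optimum()` breaks them lexicographically — smallest `theta`,
  then smallest `phi` — and reports the tie via a message.
* **Seeding.** Ensembles take one seed and restore the caller's RNG
  state. Landscape cells derive per-cell seeds deterministically from
  `(master seed, theta index, phi index)`, so cells are independent and
  the table is reproducible whatever the evaluation order. The scalar
  `run_trial()` and the vectorised engine consume identical random
  streams (two uniforms per perception, drawn unconditionally), so a
  one-trial ensemble replays `run_trial()` exactly.
* **Peak counting.** `is_single_peaked()` merges plateaus (connected
  equal-fitness cells under the 4-neighbourhood, tolerance 1e-9) before
  counting components with no strictly fitter neighbour; without the
  merge, every lattice band would count as a forest of spurious maxima.

## The default study scenario

The package's defaults define one concrete scenario used by the tests
and the acceptance script:

| parameter | value | meaning |
|---|---|---|
| `eps_good`, `eps_bad` | 0.75, 0.25 | symmetric, informative evidence |
| `prior_good` | 0.5 | even prior, drawn per trial |
| `benefit` | 10 | fitness units per correct decision |
| `k` | 0.05 | effort half-saturation cost |
| `c_time` | 0.02 | baseline cost of time |
| grid | θ: 0.55–0.99 by 0.01; φ: 0–0.98 by 0.02 | 2250 cells |
| comparison costs | 0.01, 0.02, 0.04 | halved / baseline / doubled |
| sweep | 20 log-spaced in [0.002, 0.2] | two orders of magnitude |

The evidence probabilities make a symmetric environment whose oracle is
the exact ruin form, which keeps full-grid optimisation deterministic
and fast. The cost parameters were chosen, once, so that the baseline
optimum is interior to the grid with a decision time of realistic length
(θ* = 0.88, φ* = 0.62, `DT` ≈ 11 samples) rather than a degenerate
one-sample corner: a forager that inspects ten-odd husks before
committing is the regime the trade-off is about. Under this scenario the
package reproduces the expected phenomenology: a single-peaked baseline
landscape; θ* non-increasing and φ* non-decreasing in the cost of time;
monotone substitution of effort for time along the sweep; and a flexible
(Type 1) agent that weakly dominates the fixed-effort (Type 2) agent
everywhere, strictly off baseline, while also being at least as
accurate at the halved and doubled costs.

Because fitness in oracle mode is exactly piecewise constant in `theta`,
landscapes at *some* non-default cost levels can contain a second
band-plateau that counts as a local maximum under the exact tie
tolerance; the single-peak property is asserted for the baseline
landscape. Monte-Carlo noise in simulate mode would instead fragment the
plateaus into many tiny maxima, which is why peak counting is an
oracle-mode diagnostic.

## Type 1 vs Type 2, and the substitution curve

`compare_across_time_costs()` evaluates both agent types against a
*shared* performance table per cost: the true-state dynamics do not
depend on `c_time`, so one grid evaluation serves every swept cost, and
the dominance `W(type1) >= W(type2)` plus the baseline identity
(identical cells, relative advantage exactly 0) hold exactly instead of
up to re-simulation noise. The relative fitness advantage is defined as
`(w1 - w2) / |w2|` — zero-anchored and sign-correct for the comparison
figures — with the absolute difference always reported alongside, and a
guard for a numerically zero reference. `substitution_curve()` records
the Type 1 optimum per cost: its mean decision time, per-sample effort
spend, and their product (total effort per decision).

```{r, fig.width = 6, fig.height = 4, eval = FALSE}
env <- sprt_environment()
land <- evaluate_landscape(env, cost_model(0.05), grid_spec())
autoplot(land)
autoplot(substitution_curve(env, cost_model(0.05), grid_spec()))
```

## What the simulator does and does not emulate

The stochastic generator reproduces the model world exactly as stated:
i.i.d. binary evidence, i.i.d. perceptual corruption, a memoryless
stopping rule, and a stationary environment within a decision. Passing
tests therefore show internal consistency (simulator vs two independent
oracles) and the comparative statics of *this* model; they do not show
that real foragers face binary i.i.d. evidence, that perceptual error is
state-independent, that effort maps to accuracy hyperbolically, or that
fitness is linear in accuracy and cost. Real decision streams are
typically autocorrelated, priors uneven, and effort budgets shared
across competing tasks — none of which is represented here. The model
also implements only error-reducing effort; effort that increases the
sampling *rate* per unit wall-clock time is outside its scope, as are
drift-diffusion (continuous evidence) variants and evolutionary dynamics
between the agent types.

## Problem sizes

The suite and the acceptance script use ensembles of 10^5 trials for
simulation-vs-oracle checks (binomial and exact-variance three-standard-
error bands), 10^4 trials per cell for simulated-landscape spot checks
on small grids, and the full 2250-cell grid only in oracle mode, where
each symmetric cell is a closed-form evaluation. These sizes give
standard errors around 10^-3 on accuracies while keeping a full run in
well under a minute on one core.
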