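---
title: "The optimal-Perceptron account of contraction and choice bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The optimal-Perceptron account of contraction and choice bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perceptbias)
```

## The task and its statistics

The package models a two-alternative delayed comparison: two pure tones
are presented in sequence and the observer reports which had the higher
pitch. All computation is done in relative log-frequency units
`s = ln(f / 1000)`, i.e. relative to the 1 kHz median of the stimulus
distribution. A block is parameterised by the mean
`m = (s1 + s2) / 2 ~ U(-0.2, 0.2)` and the half-difference
`d = (s1 - s2) / 2`, which on *possible* trials is
`U(-0.0905, 0.0905)` and on *impossible* trials is exactly zero
(`f1 == f2` bit-exactly). Blocks have 220 trials of which exactly 25% are
impossible; the positions of the impossible trials are shuffled uniformly.

Feedback on possible trials is always veridical. On impossible trials it
follows one of five protocols giving the probability that the response
"f1 > f2" is declared correct, separately for stimuli below and above the
median: control (0.5, 0.5), enhance/suppress "f1 > f2" (0.9, 0.9) /
(0.1, 0.1), and enhance/suppress contraction (0.9, 0.1) / (0.1, 0.9). The
rewarded response for each impossible trial is pre-drawn at generation
time, so that re-simulating an observer on the same block faces the same
reward sequence.

## The observer model

The representations entering the decision are `r1 = s1 + n` with
`n ~ N(0, sigma^2)` and `r2 = s2`: only the first, remembered stimulus is
noisy. The response is `A = Theta(a * r1 - r2 - b)`. The model's three
parameters, with units and roles:

| parameter | units | role | default |
|---|---|---|---|
| `a` | unitless | weight of the first stimulus; `a < 1` produces contraction bias | 1 |
| `b` | log-frequency units | decision criterion; `b != 0` produces choice bias | 0 |
| `sigma` | log-frequency units | SD of the memory noise on tone 1 | fitted |

Under a Gaussian prior `s1 ~ N(0, Sigma^2)` the posterior mean of `s1`
given `r1` is `r1 / (1 + sigma^2 / Sigma^2)`, so the accuracy-optimal
policy "report f1 > f2 iff E[s1 | r1] > s2" is a Perceptron with
`a = 1 / (1 + sigma^2 / Sigma^2)` and `b = 0`. `optimal_a_gaussian()`
implements this closed form. The task's actual `s1` marginal is a
uniform-uniform convolution, not Gaussian, so the package treats the
closed form as an analytic reference (`prior_spec("task_uniform")`
supplies the variance-matched `Sigma^2 = 0.2^2/3 + 0.0905^2/3`) and
computes reward-optimal parameters numerically under the true task
distribution with `optimize_params()`. The test suite verifies that the
closed form agrees with brute-force maximisation under a genuinely
Gaussian prior at `sigma/Sigma` ratios 0.25–2 to within the brute-force
grid step.

`expected_reward()` is the optimisation objective: 0.75 times the
veridical-feedback probability on possible trials plus 0.25 times the
protocol-dependent reward probability on impossible trials. Expected
*feedback* is the natural reading of optimality here; the alternative of
maximising accuracy on possible trials only would make every protocol
trivially equivalent and is not implemented.

## Numerical choices

- **Tie rule.** `Theta(0)` is undefined in the abstract model; the package
  resolves `h == 0` to `A = 0`. The event has measure zero under noise; a
  fixed rule keeps every simulation and probability deterministic.
- **Quadrature.** For `sigma * |a| > 0` the reward integrand is smooth
  within each half-range, so tensor-product Gauss–Legendre quadrature is
  used, split at `d = 0` (where the correct response flips) and `m = 0`
  (where the reward probability jumps): 48 mean-nodes by 2 x 24
  difference-nodes for possible trials, 2 x 48 nodes for impossible
  trials. Agreement with Monte-Carlo at 1e5 samples is tested at three
  standard errors.
- **Deterministic limit.** When `sigma == 0` or `a == 0` the response is
  an indicator and node-based quadrature becomes unreliable (plateaus at
  node resolution), so the expectation is reduced exactly to clipped
  half-plane lengths, integrated on a dense midpoint grid (8192 cells;
  the integrand is piecewise linear, so only kink cells carry error).
  This is what makes the zero-noise optimal weight uniquely `a = 1.000`
  at a grid step of 0.001.
- **Optimisation.** `optimize_params()` is a coarse-to-fine 13 x 13 grid
  search over `a` in [-0.5, 2], `b` in [-0.3, 0.3], shrinking the box to
  one grid cell around the maximiser until both widths fall below 1e-3.
  No stochastic optimiser is involved, so results are exactly
  reproducible. Negative `a` is allowed because contraction-suppressing
  protocols can push the optimum above 1 and hypothetical protocols could
  push it below 0.
- **Likelihood fitting.** `fit_sigma()` maximises the Bernoulli
  log-likelihood over `sigma` in [1e-3, 1]: a 201-point log-spaced grid,
  then golden-section refinement in the bracketing interval. For the
  optimal-Perceptron model `(a, b)(sigma)` is precomputed on the grid
  (cached per protocol per session) and linearly interpolated in
  `log(sigma)` during refinement. Probabilities are clipped to
  `[1e-9, 1 - 1e-9]` before logging so deterministic predictions cannot
  produce infinite penalties. Degenerate data (all responses identical,
  or a maximiser on the search boundary, e.g. noiseless observers) are
  flagged `converged = FALSE` rather than rejected.
- **Sigmoid fits.** The descriptive psychometric fits use a two-parameter
  cumulative normal, fitted by a deterministic 41 x 41 grid over
  (midpoint, log slope) followed by Nelder–Mead from the grid optimum.
  All-0/all-1 data are flagged degenerate and report the empirical
  proportion at `delta = 0`.

## Open design points and how they were settled

- **Exclusion test sidedness.** Performance screening uses an exact
  two-sided binomial test per half-block at alpha 0.05 against chance; at
  82 possible trials per half the minimal passing count is 51 (62%),
  matching the conventional screening threshold — a one-sided test would
  not.
- **Region boundaries.** The low/intermediate/high frequency regions are
  terciles of the design range of `m` (boundaries at +/- 0.2/3),
  configurable in every analysis function.
- **Impossible-trial likelihood.** Model fits include impossible trials
  by default: under the psychometric model they contribute a constant
  `log(0.5)` each, while under the optimal-Perceptron model they carry
  real information about contraction. A `possible_only` flag restricts
  the likelihood when needed.
- **Fitting under biased protocols.** The optimal-Perceptron likelihood
  maps `sigma` to the *control*-protocol optimum by default, because
  model comparison is defined for unbiased-feedback data; passing another
  protocol reuses that protocol's optimum.
- **Criterion learning rule.** The analysis of optimal parameters is
  deliberately learning-rule-free. The adaptive observer used to generate
  criterion-drift dynamics applies the simplest reward-following delta
  rule, `b <- b - eta * (2*feedback - 1) * (2*response - 1)`, which makes
  rewarded responses more likely. It is labelled plumbing: only `b`
  adapts, embodying the empirical finding that feedback reaches the
  decision stage but not the representation stage. Default
  `eta = 0.02` log units per trial gives clear drift within a 220-trial
  block at `sigma = 0.1` while keeping trial-to-trial jitter small.
- **Noise population.** Real per-observer noise values are not published,
  so cohort simulations default to a log-normal stand-in with median
  0.08 log units and `sdlog` 0.5 — discrimination thresholds in the
  right range for this task — and every analysis accepts arbitrary
  distributions (`fixed`, `uniform`, `lognormal`).

## What the generator does and does not emulate

The synthetic cohorts reproduce the stimulus statistics, block structure,
feedback contingencies, exclusion screening and the two-stage observer
architecture. They do **not** emulate lapses of attention, fatigue or
learning of `a` and `sigma`, asymmetric noise on the second stimulus, or
any auditory-periphery nonlinearity. Passing tests therefore demonstrate
the internal consistency of the pipeline and the model-level claims
(optimality of `a < 1` under noise, feedback sensitivity of `b` but not
`a`, recoverability of `sigma`), not fidelity to any particular human
cohort: headline human counts from the original study population are out
of reach by design.

## Problem sizes

The test suite simulates cohorts of 10–34 observers with 220–1000 trials
per block, recovery studies with 20 observers per noise level
(`sigma` in {0.05, 0.1, 0.2}, 220 trials each), and Monte-Carlo checks at
1e4–1e5 draws; these sizes give three-standard-error resolution well
below the effect sizes being asserted while keeping a full run of the
suite within a few minutes on one CPU core.

## Known limitations

- The deterministic-limit reward computation is exact only up to the
  dense-grid kink cells (~1e-5 relative); an analytic polygon clip would
  remove even that.
- `fit_sigma()` gives no confidence interval for `sigma`; profile-based
  intervals would be a natural extension.
- The adaptive criterion has no forgetting or top-down symmetry prior, so
  under strongly biased feedback `b` drifts without bound; over 220-trial
  blocks this is the intended saturating choice bias, but longer runs
  would need a leaky rule.
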