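# perceptbias

Simulation and analysis of **delayed two-tone frequency discrimination**
with manipulated feedback, built around a noisy-representation Perceptron
model of the two classic perceptual biases:

- **Contraction bias** — the remembered first tone is pulled toward the
  center of the stimulus distribution, so the indifference line in the
  (log f1, log f2) plane has slope < 1.
- **Choice bias** — a stationary preference for one response, a parallel
  shift of that line.

The package is for computational psychophysicists who want to (i) generate
trial blocks with the task's exact stimulus statistics and feedback
contingencies, (ii) simulate observer cohorts, (iii) fit the internal-noise
parameter of one-parameter choice models by maximum likelihood, and (iv)
run the descriptive analyses that dissociate the feedback-sensitive choice
bias from the feedback-insensitive contraction bias.

## The model

On each trial two tones with frequencies f1, f2 (log-uniform around a
1 kHz median) are compared. Stimuli are expressed in relative log units
`s = ln(f / 1000)`. The internal representations are

    r1 = s1 + n,   n ~ N(0, sigma^2)      (memory noise on tone 1 only)
    r2 = s2                                (noiseless)

and the observer's report "f1 > f2" is the step decision

    A = Theta(h),   h = a * r1 - r2 - b.

The weight `a` maps to contraction bias and the criterion `b` to choice
bias. With a Gaussian prior `s1 ~ N(0, Sigma^2)`, Bayes' rule gives the
posterior mean `mu = r1 / (1 + sigma^2 / Sigma^2)`, so the reward-optimal
weight is

    a* = 1 / (1 + sigma^2 / Sigma^2),   b* = 0   (unbiased feedback)

— equal to 1 only at `sigma = 0` and decreasing with noise: contraction
bias is the signature of an optimal observer with noisy memory. For any
feedback protocol, `optimize_params()` finds the `(a*, b*)` maximizing the
expected feedback rate by deterministic quadrature and grid refinement.

Blocks have 220 trials; 25% are "impossible" (f1 = f2), where feedback
follows one of five protocols (`control`, `enhance_f1gt`, `suppress_f1gt`,
`enhance_contraction`, `suppress_contraction`) that reward "f1 > f2" with
probability 0.1/0.5/0.9 depending on the side of the 1 kHz median.

## Worked example

```r
library(perceptbias)

blk <- generate_block("control", n_trials = 220, seed = 101)
obs <- simulate_static_observer(
  observer_spec("static", a = 0.8, b = 0, sigma = 0.12, seed = 102), blk)
obs
#> Trial log: 220 trials (55 impossible), protocol 'control', observer 'obs1'
#>   accuracy on possible trials: 0.764

exclusion_test(obs)$decision
#> [1] "keep"

fit_p <- fit_sigma(obs, model = "optimal_perceptron")
fit_q <- fit_sigma(obs, model = "psychometric")
fit_p
#> Choice-model fit (optimal_perceptron)
#>   sigma_hat = 0.1393  (a = 0.6060, b = 0.0000)
#>   log-likelihood = -119.13 over 220 trials (-0.5415 per trial)

compare_models(fit_p, fit_q)
#> Model comparison over 1 observers
#>   mean dLL/trial (Perceptron - psychometric): 0.03371
#>   fraction favoring the Perceptron: 1.00 (sign test p = 1)

contraction_magnitude(obs)
#> Bias summary
#>   contraction magnitude (fitted curves at f1 = f2): 0.393
#>   contraction magnitude (impossible-trial fractions): 0.333 (1 observers)
#>   choice bias (region-II midpoint): 0.0009
```

The simulated observer under-weights the first tone (`a = 0.8`), and both
readouts agree: the optimal-Perceptron model fits its choices better than
the psychometric curve (positive log-likelihood difference per trial), and
the low-range vs high-range psychometric curves are separated at f1 = f2
by ~0.35 — the contraction-bias magnitude. `run_pipeline()` scales this
workflow to multi-protocol cohorts and writes tidy CSV tables, figures and
a JSON summary.

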