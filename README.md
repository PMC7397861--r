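# actionprior

Precision-weighted observer models of how people perceive their own action
outcomes.

In force-aiming tasks, people launch a cursor ("ball") toward a target by
pressing a force sensor, and on a minority of trials — with the trajectory
hidden — report where they believe the ball stopped. Their reports are not
veridical: they are pulled toward the target, consistent with a Bayesian
observer that combines noisy sensory evidence about the true outcome with a
prior belief centred on the goal. `actionprior` implements the full
computational pipeline for such experiments, exercised end-to-end on
synthetic cohorts with known ground truth, and relates the estimated prior
precision to trait apathy scores.

## The model

On an estimation trial with true final position $x_\text{true}$ and target
$\mu_\text{prior}$, the reported estimate is

$$x_\text{estimate} = w\,\mu_\text{prior} + (1-w)\,\mu_\text{evidence},
\qquad
w = \frac{\sigma^2_\text{evidence}}
         {\sigma^2_\text{evidence} + \sigma^2_\text{prior}},$$

with $\mu_\text{evidence} = x_\text{true} + s$ allowing a directional shift
of the sensory evidence. Equivalently, the estimation error regresses on
the performance error with slope $-w$: a slope of $-1$ is full reliance on
the prior, $0$ a disregard of it. The package estimates
$\sigma_\text{prior}$, $\sigma_\text{evidence}$ and $s$ per participant and
condition with a three-level hierarchical Bayesian model (group →
participant → condition, MCMC via JAGS), compares observer variants by
WAIC, and tests the association between prior precision and apathy with
partial correlations (adjusting for performance variability), Holm
correction and Jeffreys exact correlation Bayes factors.

What the package provides, stage by stage:

- **Task core** — deterministic task geometry and physics
  (`force_to_position()`), seeded trial scheduling (`generate_schedule()`),
  maximum-force calibration, and the linear reward rule.
- **Synthetic cohorts** — `sample_cohort()` + `simulate_trials()` generate
  trial-level data with known observer parameters, performance biases, and
  a trait score linked to prior SD at a target partial correlation.
- **Preprocessing** — participant exclusion and trial filtering by scaled-MAD
  rules, first-trial removal, performance summaries.
- **Behavioural statistics** — balanced 2×2 repeated-measures ANOVA with
  generalized eta-squared; ANCOVA with a continuous covariate.
- **Weighting regression** — ten candidate linear mixed models of
  estimation error on performance error, selected by conditional AIC.
- **Observer models** — hierarchical Bayesian fits (`fit_observer()`),
  split-R̂ diagnostics, WAIC comparison, posterior predictive checks,
  parameter-recovery scoring.
- **Trait association** — `partial_correlation()`, `holm_adjust()`,
  `jzs_correlation_bf()`, exact power analysis
  (`sample_size_for_correlation()`).
- **Pipeline** — `run_pipeline()` orchestrates everything from one seeded
  config and writes a machine-readable report.

## Worked example

```r
library(actionprior)

# a compact task: 8 blocks x 27 trials, 80 estimation trials/participant
cfg   <- task_config(blocks_per_condition = 2, n_blocks = 8,
                     estimation_per_block = 10, basic_per_block = 17)
truth <- sample_cohort(12, cfg, seed = 101)
trials <- simulate_trials(truth, seed = 102)
pre   <- preprocess_trials(trials)

# how strongly do estimates lean on the prior?
wfit <- fit_weighting_model(pre$trials)
wfit
#> <ap_weighting_fit> i_none.s_none
#>   slope = -0.686 (weighting w = 0.686); cAIC = 7754.0 (edof 17.1)

# hierarchical observer fit (shifted-evidence variant, demonstration scale)
fit <- fit_observer(pre$trials, "m2", chains = 2, draws = 250,
                    warmup = 400, adapt = 400, thin = 2, seed = 103)
fit
#> <ap_observer_fit> variant m2 (sensory likelihood)
#>   11 participants, 873 estimation trials; 2 chains x 250 draws
#>   max split R-hat = 1.1866; mean weighting w = 0.70
```

The weighting slope of −0.69 says estimates moved about 69% of the way from
the true outcome toward the target; the generating cohort's mean weighting
was 0.66, and both routes (mixed model and hierarchical observer) land on
it. The short demonstration chains above do not meet the convergence
contract (note the R̂ of 1.19); converged analyses use the default
4 chains × 500 thinned draws, under which every parameter's split R̂ falls
below 1.01.
`parameter_recovery(truth, fit)` scores posterior means against the
generating parameters, and `compare_waic()` contrasts the three observer
variants (target prior; target prior + sensory shift; observational prior).

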