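---
title: "Precision-weighted observer models of action-outcome perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Precision-weighted observer models of action-outcome perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(actionprior)
```

## The scientific problem

In the force-aiming task this package models, a participant presses a force
sensor to launch a ball across the screen toward a target; the initial
velocity, and hence the final position, is a deterministic function of the
applied force. Most trials show the full trajectory ("basic" trials), but on
interleaved "estimation" trials the trajectory is hidden and the participant
reports where they believe the ball stopped. Reports are systematically
biased toward the target. The package treats this bias as rational
perception: a Bayesian observer combines noisy sensory evidence about the
true outcome with a prior belief that the action succeeded, weighting each
by its precision. The narrower the prior, the stronger the pull toward the
goal. Estimating each person's prior precision, and relating it to trait
apathy, is the pipeline's purpose: the working hypothesis is that apathetic
individuals hold *less* precise priors over their action outcomes.

## The observer model

On an estimation trial with true outcome $x_\text{true}$ and prior mean
$\mu_\text{prior}$ (the target position), the reported estimate is modelled
as

$$x_\text{estimate} = w\,\mu_\text{prior} + (1-w)\,(x_\text{true} + s),
\qquad
w = \frac{\sigma^2_e}{\sigma^2_e + \sigma^2_p},$$

where $\sigma_p$ is the prior SD, $\sigma_e$ the sensory-evidence SD, and
$s$ a signed sensory shift capturing systematic perceptual distortions
(e.g. from the ball's rightward motion). Three variants are fitted by
`fit_observer()`:

* **m1** — target-centred prior, no shift ($s \equiv 0$);
* **m2** — target-centred prior plus the shift $s$ (m1 is nested in m2);
* **m3** — "observational" prior: the prior mean and SD are *fixed* at the
  participant-condition's empirical mean and SD of basic-trial outcomes, so
  only $\sigma_e$ is free. This asks whether the prior merely reflects the
  statistics of one's true performance.

Rearranging the estimate equation gives the package's second, independent
route to $w$: the estimation error regresses on the performance error with
slope $-w$ and intercept $(1-w)s$. `fit_weighting_model()` exploits this
with linear mixed models; simulation-based tests confirm both routes
recover the same generating $w$.

### Trial-level likelihood

The task's data sources do not pin down the trial-level noise model, so the
package isolates the choice behind one function. The default
(`likelihood = "sensory"`) treats each report as built from a single noisy
sensory sample $x_s \sim \mathcal N(x_\text{true} + s,\, \sigma_e^2)$
passed through the weighting, giving a Gaussian likelihood with SD
$(1-w)\,\sigma_e$. The alternative (`likelihood = "posterior"`) uses the
Bayes-posterior SD $\sqrt{1-w}\,\sigma_e$. Both are available in
`fit_observer()` and `loglik_estimation_trial()`; the synthetic-data
generator draws from the sensory-sample model, and no separate motor or
pointing noise is added by default.

## Hierarchy, priors, and the sampler

Parameters live at three levels: group → participant → condition, with one
$(\sigma_p, \sigma_e)$ pair per participant-condition cell. Positivity is
enforced by modelling the log SDs; cell-level deviations around each
participant's mean are Gaussian on the log scale. Hyperpriors are weakly
informative: diffuse normals on group means, half-normal(1) on the
between/within SDs of the log-scale parameters, and half-normal(20) on the
shift hyperparameters (pixel scale).

Two parameterization choices matter for sampling and were settled by
convergence experiments at the package's desk scale before any analysis
settings were frozen:

1. **Non-centred condition level.** With ~20 estimation trials per cell the
   data are only moderately informative about each cell's log SDs, and the
   centred parameterization produced the classic funnel (split-R̂ up to
   1.07 at 500 retained draws). Cell deviations are therefore sampled as
   standard normals scaled by the within-participant SD.
2. **The shift enters through its identified projection.** The likelihood
   constrains the intercept $\alpha = (1-w)s$, not $s$ itself, and $s$
   rides a posterior ridge with $w$. The sampler therefore works with
   $\alpha$ directly (an exact change of variables), and $s$ is recovered
   deterministically.

The shift's sharing level is configurable. By default $s$ is one parameter
per participant (`shift_level = "participant"`): a per-cell shift adds a
within-participant shift-SD layer that is weakly identified at desk scale
and reintroduces a funnel, while perceptual distortions of this kind are
plausibly a property of the observer rather than of the effort or reward
condition. `shift_level = "cell"` frees it per condition.

Sampling runs in JAGS with per-chain seeded generators, so fits are exactly
reproducible for a fixed seed. The desk-scale default is 4 chains × 500
retained draws with thinning 20 after 1,000 adaptation and 1,000 burn-in
iterations (about 7 minutes for 30 participants × 80 estimation trials on
one core); convergence is declared only when every parameter's split-chain
R̂ is below 1.01. The full-scale setting of 8 chains × 2,000 draws is a
matter of passing `chains` and `draws`.

Model comparison uses WAIC computed from the pointwise log-likelihood
matrix with log-sum-exp stabilisation; `compare_waic()` reports pairwise
differences with standard errors from the pointwise contributions
($\mathrm{SE} = \mathrm{sd}(\Delta_i)\sqrt{n}$). Posterior predictive
checks (`posterior_predictive()`) replicate estimate sets from posterior
draws and summarise central-interval coverage per condition.

## What the synthetic cohorts emulate

`sample_cohort()` draws ground-truth parameters from group-level
distributions chosen to mimic the qualitative structure of real cohorts in
this task family; they are the package's study conditions, fixed in
`cohort_settings()`:

* prior SD around 40 px (log-normal across participants, SD 0.30), loading
  0.45 on the participant's standardized log performance variability — this
  induces the strong positive correlation between prior SD and performance
  SD seen empirically, while keeping the prior SD well below the
  pixel-scale performance SD (~110–170 px) for nearly all participants;
* evidence SD around 65 px, giving a group mean weighting $w \approx 0.7$;
* a leftward sensory shift, mean −15 px, SD 8 px across participants;
* performance in % of maximum force: undershoot bias of −3% under high
  effort vs −0.5% under low, SD 5% scaled ×1.5 by high effort and ×0.9 by
  reward — high effort degrades accuracy and variability, reward improves
  both;
* a behavioural-activation apathy score constructed by `link_trait()` so
  that its partial correlation with the participant-mean prior SD, given
  performance variability, targets 0.37 (subscale means are simulated
  directly on the 0–4 scale; item-level responses are not modelled).

The generator reproduces the statistical structure the analysis assumes —
it does not emulate learning or adaptation across trials, fatigue, motor
noise beyond the Gaussian force model, or item-level questionnaire
behaviour. Passing recovery tests therefore show that the estimation
machinery is correct and well calibrated under the model's own assumptions,
not that the model is true of any real cohort.

## Numerical and statistical conventions

* **Scaled MAD filters.** Both the participant-exclusion rule and the
  trial filter use the median absolute deviation with the 1.4826
  consistency constant. A zero MAD disables the rule for that group with a
  warning rather than deleting every non-median value. "Average task
  performance" for exclusion is the participant's mean absolute force
  error, the natural magnitude summary when bias can take either sign.
* **Quartiles** are type-7 (linear interpolation), fixed so tests are
  exact.
* **Generalized eta-squared** uses the fully-within convention (subject
  variance in the denominator; Bakeman 2005). With 1-df effects in the 2×2
  design no sphericity correction applies.
* **Conditional AIC.** Candidate weighting models are fitted by ML (not
  REML) so conditional likelihoods are comparable; the effective dof is
  the trace of the conditional hat matrix (Vaida–Blanchard) plus one for
  the residual variance, computed from the mixed-model equations with a
  vanishing ridge so that zero variance components degrade gracefully to
  the fixed-effects AIC. Several bias-corrected cAIC variants exist; the
  hat-trace version is the documented choice.
* **Partial correlations** use the correlation-matrix formula, p-values
  from the t transform with $n-3$ df (one covariate), and a four-test Holm
  family (total score plus three subscales).
* **Correlation Bayes factors** are Jeffreys's exact test: uniform
  stretched-beta prior on $\rho$, marginalising the exact sampling density
  of $r$ (evaluated via a Gauss $_2F_1$ series), with the effective sample
  size reduced by one per covariate for partial correlations. This choice,
  rather than the one-dimensional $g$-prior integral, reproduces published
  Bayes factors for this task family within rounding of their inputs.
* **Power analysis** defaults to the exact method — integrating the exact
  sampling density of $r$ over the two-sided rejection region — which
  requires 46 participants to detect $\rho = 0.4$ at 80% power
  ($\alpha = .05$); the Fisher-z closed form returns 47 and is kept as the
  documented approximation.
* **Degenerate inputs** (constant cells, zero variances, empty inputs,
  single MCMC draws) return conventioned values with warnings or explicit
  errors, as documented per function.

## Task geometry

Target positions and the force-to-position map are calibrated jointly: the
nominal effort force (35% or 65% of maximum) must land exactly on its
target centre (512 or 896 px from the left margin, start at 128 px). Under
the quadratic distance law $d = v^2/2a$ a *single* deceleration constant
cannot satisfy both anchors (the target distances have ratio 2 while the
squared nominal velocities have ratio ≈ 3.45), so the package calibrates
one deceleration per effort level and treats the nominal-force anchors as
exact. Schedules place estimation trials by rejection sampling under the
design constraints (first three trials of each block basic, no two
estimation trials adjacent), which is fast because valid arrangements make
up a few percent of random ones.

## Problem sizes

The test-suite and acceptance runs use a compact task configuration — 8
blocks of 27 trials, 10 estimation trials per block, hence 80 estimation
trials per participant (20 per condition) — and cohorts of 12–30
participants, sizes at which every property under test (convergence below
R̂ = 1.01, parameter recovery above r = 0.7, WAIC model recovery, the
slope ↔ weighting identity within ±0.05) is comfortably measurable on a
single core. The full design (40 blocks, 1,080 trials, 47 participants) is
a configuration change, not a code path.

## Known limitations

* The exact hierarchical priors of the original task family are not public
  in print; the half-normal hyperpriors here are the package's documented
  choice and should be reconciled against any upstream model release.
* The trial-level likelihood is an assumption (see above); the two
  implemented variants bracket the plausible choices but are not exhaustive
  (no lapse process, no report/motor noise).
* WAIC is the only information criterion implemented; cross-validation
  (LOO) is out of scope.
* Mixed models are Gaussian with participant-nested random effects only;
  crossed designs are not supported.
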