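---
title: "Modelling camera-trap trigger probability from experimental detection trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling camera-trap trigger probability from experimental detection trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camtrigger)
```

## The problem

Camera traps miss animals. An animal can walk through a camera's field of
view and never fire the passive-infrared (PIR) sensor, because its heat
signature is too small, too far away, too low in the sensor cone, or washed
out by solar heating of the background. The probability that a passing
animal actually triggers the camera, written $r_t$, is one of three
conditional probabilities that together determine whether an animal is
observed at all in a monitoring interval with $N$ visits:

$$p = 1 - \left[1 - (r_e \cdot r_t \cdot r_p)\right]^{N},$$

where $r_e$ is the probability of encountering the camera's sample unit and
$r_p$ the probability that a triggered image is usable
(`combined_detection_probability()`). This package implements an
experimental and analytical framework for estimating $r_t$ from controlled
detection trials: passes of standardized body-size proxies in front of
cameras at known distances, scored as detected (1) or missed (0).

## The two-stage model

**Stage 1 — distance detection functions.** Trial outcomes are Bernoulli
with a success probability that declines with distance $y$ (metres).
Three classical distance-sampling detection-function families are adapted
to this binomial response:

* exponential: $p(y) = \exp(-y/\alpha)$
* half-normal: $p(y) = \exp\!\left(-y^2 / (2\alpha^2)\right)$
* hazard-rate: $p(y) = 1 - \exp\!\left(-(y/\alpha)^{-\gamma}\right)$

with scale $\alpha > 0$ (m) and, for the hazard family, shape $\gamma > 0$.
Each family can be multiplied by a logistic-in-distance mixture term
$\left[1 + e^{-(y - m)s}\right]^{-1}$, which allows *low* detection
immediately in front of the camera — animals passing beneath the sensor
cone — with midpoint $m \ge 0$ (m, where the base curve is halved) and
steepness $s > 0$ (per m). The mixture adds exactly two parameters, so the
six candidates have $K \in \{1, 1, 2, 3, 3, 4\}$. Parameters are estimated
by maximizing the Bernoulli log-likelihood
(`fit_detection_function()`) and candidates ranked by
$\mathrm{AIC} = 2K - 2\,\mathrm{LL}$ (`select_model()`). The winner by
minimum AIC is carried into stage 2.

**Stage 2 — covariate regression.** A logit-link binomial GLM relates each
trial outcome to the experimental covariates — body-size proxy, camera
model, lens height (cm), aiming distance (m), vertical camera angle
(degrees), trial speed (m/s), sun altitude and azimuth (radians) — plus
the *distance model* covariate: the stage-1 fitted probability
$\hat p(y_i)$ evaluated at the trial's distance (`fit_logit()`). Stage-1
parameters are fixed at their MLEs; their sampling uncertainty is not
propagated into stage-2 standard errors. Interactions of body size and
camera model with the distance model capture how distance effects are
mediated by target size and sensor geometry. Backwards stepwise selection
(`backward_stepwise()`) drops the least-significant term with joint Wald
$p > 0.05$ at each step, under a marginality rule (a main effect is frozen
while any interaction containing it remains) and with categorical contrast
blocks tested and removed jointly. Final models are evaluated by ROC/AUC
(`roc_auc()`), and effects are communicated as marginal effects: the mean
predicted probability over the observed trials with the focal covariate
set counterfactually to each grid value, with delta-method standard errors
(`marginal_effects()`).

Because vertical angle is strongly rank-correlated with lens height and
aiming distance in realistic deployments (they jointly determine where the
sensor cone points), the covariates are split into two separately fitted
suites — an angle suite and a height + aiming suite (`suite_terms()`);
`collinearity_check()` computes the Spearman diagnostic that motivates the
split.

## Design choices worth knowing about

* **Scale of the distance-model covariate.** The stage-1 prediction enters
  stage 2 on the raw probability scale (0–1), not as a logit or linear
  predictor. Coefficients of several log-odds units on this term are then
  directly interpretable as the contrast between detection at point-blank
  range and far beyond the detection zone.
* **Mixture form.** The near-camera miss process is modelled
  multiplicatively: base curve × logistic ramp. The two extra parameters
  match the candidate table's $K$ column; other mixture variants (e.g. a
  mixing weight between two curves) would change the parameter count.
* **Likelihood details.** Probabilities are clamped to
  $[10^{-12}, 1 - 10^{-12}]$ inside the likelihood, since the hazard
  family reaches $p \to 1$ as $y \to 0$ and the mixture reaches $p \to 0$.
  The hazard curve is evaluated as exactly 1 at $y = 0$ (its limit).
* **Optimization.** The mixture likelihood surface can carry several local
  maxima. Fitting therefore optimizes log-transformed parameters from a
  deterministic multi-start grid (scale starts 2, 5, 10, 15, 25 m, crossed
  with mixture midpoints 0.5 and 2 m), Nelder–Mead followed by a BFGS
  polish, keeping the best optimum; one-parameter families use Brent's
  method on $\alpha \in [10^{-3}, 10^{3}]$. Degenerate inputs (all trials
  detected, or all missed) return a non-converged fit with a boundary
  diagnostic instead of a spurious optimum.
* **Stepwise testing.** "Significant" means a two-sided Wald test at
  0.05. Factor blocks are decided per factor, not per contrast, so a
  non-significant contrast survives while its sibling contrast keeps the
  block in the model.
* **AIC, not AICc**, matching the $2K - 2\mathrm{LL}$ identity used in the
  ranking table.

## The synthetic experiment

Real trial data of this kind are rarely deposited, so the package carries
a first-class simulator (`simulate_trials()`). Its defaults define a
standard synthetic experiment mirroring the balanced factorial layout used
in field calibrations of this design: 3 body-size proxies × 2 camera
models × 3 lens heights (86, 116, 146 cm) × 3 aiming distances (5, 10,
15 m) × 7 distances (2, 4, 6, 8, 10, 12, 15 m) × 10 replicates = 3780
trials (`generate_design()`). The true stage-1 model is a half-normal
logistic mixture with $\alpha = 6$ m, midpoint 1.5 m and steepness 3 per m
— fixture values, not estimates from any field study. Trial speed is
normal with mean 1.0 and SD 0.3 m/s, truncated at zero. Vertical angle is
derived from mounting geometry ($\arctan$ of lens height over aiming
distance, plus 0.5° of set-up noise), which reproduces the angle–height
collinearity that motivates the two-suite analysis. Sun covariates are
drawn uniformly (altitude 0.05–1.2 rad, azimuth 0–$2\pi$) by default; a
NOAA-style low-accuracy solar ephemeris (`solar_position()`) is available
when simulated trials should carry real sun geometry for a site and time
window. Default stage-2 coefficients are moderate fixture effects
(`default_sim_coefficients()`).

With `coefficients = NULL` the covariate layer is dropped and outcomes are
drawn directly as $\mathrm{Bernoulli}(p(y))$ from the detection function —
a pure stage-1 calibration experiment.

What the simulator does *not* emulate: repeated passes by real animals
(sinuous paths, variable entry angles), PIR physics (temperature
differentials, sensor-zone geometry), temporal autocorrelation between
trials, and site heterogeneity. Passing tests on synthetic data
demonstrate that the estimators recover the parameters of the assumed
model, not that the model describes any particular field system.

## Validating the two-stage pipeline

A subtlety drives the design of the package's recovery experiment. If
synthetic outcomes are generated from the full two-stage model — a logit
GLM stacked on a detection function — the *marginal* detection-distance
curve is no longer a member of the generating family: the inverse-logit
layer imposes a floor at $\mathrm{logit}^{-1}(\beta_0)$ far from the
camera and an S-shaped distortion elsewhere, and the flexible hazard
mixture then wins the AIC ranking essentially always. Likewise, a stage-2
fit conditioned on a detection function re-fitted to such data regresses
on a nonlinearly distorted covariate, biasing the distance-model
coefficient by far more than its standard error. Neither failure reflects
a defect in the estimators; both reflect a generative model whose stage-1
"truth" is not what stage 1 estimates.

The recovery experiment therefore mirrors how the framework is actually
used, in two phases per replicate:

1. **Stage-1 calibration experiment**: 3780 outcomes drawn from the true
   half-normal logistic mixture over the factorial design; all six
   candidates fitted; scored on whether AIC selects the generating family.
2. **Stage-2 experiment conditioned on the fitted model**: outcomes drawn
   from known covariate coefficients plus the *fitted* stage-1 prediction
   as the distance covariate, then fitted conditioning on that same
   stage-1 model; scored on 95% Wald coverage of every coefficient.

This is exactly the conditioning logic of the two-step analysis — the
second stage treats the estimated detection function as known — and makes
both properties attainable and meaningful. The test suite runs 50
replicates at n = 3780 and requires ≥ 80% family recovery and ≥ 90%
per-coefficient coverage; `scripts/acceptance.R` re-runs a 30-replicate
version and reports the rates.

## A worked example

```{r example, eval = FALSE}
library(camtrigger)

# a synthetic 3780-trial experiment
trials <- simulate_trials(simulation_config(seed = 1))

# stage 1: fit the six candidates and rank by AIC
fits <- fit_all_detection_functions(trials)
select_model(fits)

# stage 2: angle suite conditioned on the selected detection function
best <- fits[[select_model(fits)$model[1]]]
fit <- fit_logit(trials, suite_terms("angle"), best)
backward_stepwise(fit)

# evaluation and marginal effects
roc_auc(trials$outcome, predict_probability(fit, trials))
marginal_effects(fit, trials, "distance_m", grid = c(2, 4, 6, 8, 10, 12, 15))
```

The same workflow is available from the shell through `exec/camtrigger`
(subcommands `design`, `simulate`, `fit-detfun`, `select`, `fit-glm`,
`evaluate`, `marginal`, `run-all`).

## Known limitations

* Stage-1 uncertainty is ignored in stage 2, so stage-2 standard errors
  are slightly anticonservative when the detection function is estimated
  from the same (or a small) calibration dataset.
* The detection function carries no covariates; systems where the distance
  profile itself changes shape with body size or camera model need a
  richer stage-1 model than this package fits.
* Sun angles enter the regression linearly in radians; strongly circular
  designs (trials spanning the full azimuth circle with nonmonotone
  effects) would need a harmonic encoding.
* The simulator's vertical angle is purely geometric; it cannot emulate
  deployments where the operator deliberately decouples angle from height.
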