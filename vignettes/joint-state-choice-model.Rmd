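---
title: "Modelling day-to-day motivation and effort-based choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling day-to-day motivation and effort-based choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emamot)
```

# The scientific problem

Effort-based decision-making tasks are usually administered once, under the
assumption that the reward and effort sensitivities they estimate are
trait-like. Intensive longitudinal (ecological momentary assessment, EMA)
designs challenge that assumption: motivation fluctuates from morning to
afternoon and day to day, and those fluctuations may move the computational
parameters themselves. `emamot` implements a complete analysis pipeline for
such a design: twice-daily Likert reports of momentary motivation (plus
happiness, fatigue and sleep quality) over two weeks, with a 24-trial
effort-reward discounting game on alternate days, trait apathy as a
between-person factor score, and a joint hierarchical Bayesian model that
couples the latent motivational state to the choice parameters.

# The joint generative model

## Latent state from binarized item endorsements

Each of the four motivation items (the reverse-worded item is reverse-scored
at ingest) is binarized: the three "true" categories (5-7 on the 7-point
scale) count as endorsement, everything else - including the neutral
midpoint - as disagreement. Endorsements follow a one-parameter (Rasch-type)
item response model,

$$P(Y_{i,t,n} = 1) = \mathrm{logit}^{-1}(\theta_{i,t} - \delta_n),$$

with item difficulties $\delta_n \ge 0$ (truncated normal(0,1) prior). The
latent state decomposes into a group mean per occasion plus a person offset,

$$\theta_{i,t} = \theta_{\mu t} + \tilde\theta_{i,t},$$

and the *missing-data rule* holds exactly: an occasion without a report has
no offset parameter, so its state equals the group mean. Offsets are
hierarchical, $\tilde\theta_{i,t} \sim N(0, \sigma_\theta)$ with a
half-normal(0,1) prior on $\sigma_\theta$ (sampled non-centered).

## State-modulated effort discounting

On game occasions, the subjective value of the harder option on a trial is a
linear discount,

$$v = \mathrm{rewSens}_{i,t}\,\Delta R - \mathrm{effSens}_{i,t}\,\Delta E,
\qquad \text{choice} \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(v)),$$

where $\Delta R$ (coins) and $\Delta E$ (effort fraction) are the option
differences. We read the per-trial value rule as an option-difference rule
entering a single Bernoulli logit - the only reading consistent with a
two-alternative outcome. Both differences are *scaled* by the design-grid SD
so the two sensitivities live on comparable scales, but never centered (a
zero difference must mean indifference); a raw-unit mode is available via
`joint_model_spec(standardize_design = FALSE)`.

Each sensitivity is a linear function of trait, an individual per-game
offset, and the within-person z-scored latent state:

$$\mathrm{rewSens}_{i,t} = \beta_{traitR}\,\mathrm{apathy}_i +
\widetilde{\mathrm{rewSens}}_{i,t} + \beta_{stateR}\, z(\theta_{i,t}),$$

and analogously for effort. The z-scoring (per participant, over that
participant's valid occasions, $n-1$ denominator) decorrelates the state
effect from trait level. Modulation weights have weakly informative
normal(0,1) priors; offsets are hierarchical with population means
($N(0,2)$ priors) and half-normal(0,1) scales. Offsets are independent
per participant x game around a common population mean; a per-participant
pooled variant was considered and rejected as the default because the
test-retest analyses should not inherit smoothing from the model.

In the lagged variants the current-state term on the reward side is replaced
by the previous and next (or previous and second-previous) *valid* occasions'
states; game cells without such an occasion contribute a zero lag term
(logged). The effort side always uses the current state.

## Inference

The backend is a Hamiltonian Monte Carlo sampler written in C++
against the exact joint log density with analytic gradients (verified in the
tests against finite differences and against a naive loop-based oracle to
1e-10). Warmup uses dual averaging toward an acceptance rate of 0.8 and a
diagonal metric estimated from a mid-warmup window; path lengths are
jittered uniformly up to `l_max` leapfrog steps. Defaults are 4 chains of
1,000 + 1,000 iterations with a convergence gate of split-Rhat <= 1.01 and
effective sample size >= 400 on the modulation weights; simulation harnesses
use shorter chains and report the gate as a flag rather than an error.

Posterior summaries follow the interval conventions of the EMA literature:
90% highest-density intervals (shortest window over sorted draws, leftmost
tie) and the probability of direction (share of draws with the sign of the
median; exact zeros count with the median's sign - a measure-zero event,
logged).

## The two-stage lag comparison

`lag_comparison()` first fits the current-state model, then refits with past
and future states replacing the current term, both given the *empirical
prior* - a normal with the stage-1 posterior mean and SD of the
current-state effect. This sharpens the lagged posteriors but also pulls
both terms toward the (positive) current-state estimate; with autocorrelated
states the current-state estimate partly reflects the past coupling, so the
future term sits above zero even when its true coupling is null. The
acceptance harness therefore runs this analysis at a deliberately small
replicate size, where the likelihood is wide enough for the future interval
to cover zero while the past effect remains directionally decisive; at large
data sizes the empirical-prior pull dominates and the future interval
excludes zero spuriously. This is an intrinsic property of the two-stage
procedure, not of the sampler.

# The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 155 recruited
participants, a baseline session plus 2 notifications/day for 14 days (29
occasions), games of 24 trials (2 catch) on alternate days counterbalanced
4/4 morning/afternoon starting on a Thursday, trait apathy standard normal,
near-unity trial success (0.98), and trait-dependent attrition.

Key generative choices:

* **Latent state.** $\theta$ = level (trait loading -1.15 x apathy + person
  intercept SD 1.0, so the trait explains about half the between-person
  variance in mean state) + Thursday-Sunday uplift (0.25 latent) + AR(1)
  fluctuation (SD 1.4, coefficient 0.62, per-person coefficient reduced by
  0.10 x apathy to mirror the weaker inertia of more apathetic people).
* **Likert emission.** Responses come from an ordered-threshold model on
  $\theta - \delta_n$ plus standard logistic noise with the 4/5 boundary at
  zero, so binarization recovers the IRT endorsement probability *exactly*;
  the full 1-7 responses exist only for the descriptive analyses.
* **Calibration.** The emitted (ordinal, person-centered) state shows
  attenuated versions of the latent correlations, so the latent constants
  were calibrated - once, by simulation at large n, then frozen - so that the
  *observed* data hit the descriptive targets: within-day lag-1
  autocorrelation ~ 0.31, state-happiness/fatigue/sleep within-person
  correlations ~ +0.51/-0.43/+0.24, normalized weekday split difference
  ~ -0.13, trait R^2 ~ 0.5, ~83% retention at the 70%-valid rule with modal
  completion 28/29. Two attenuation sources matter: ordinal emission noise
  (sum-score reliability ~ 0.78) and person-centering of a short
  autocorrelated series (which biases lag-1 slopes down by roughly
  $(1+4\phi)/T$).
* **Choices.** Population sensitivities 1.19 (reward) and 0.78 (effort) in
  standardized design units, person/game offset SDs 0.5/0.3 and 0.4/0.25,
  trait weights -0.25/+0.10, current-state reward coupling 0.19 and no
  effort coupling by default; lagged couplings are available for the
  directionality analyses. Catch trials present a dominated option and are
  chosen "wrongly" with probability 0.03.
* **Missingness.** A participant is low-engagement with probability
  `plogis(-1.7 + 0.5 apathy)` (per-occasion miss probability uniform
  0.35-0.75, guaranteed below the 70% rule); engaged participants miss
  occasions with Beta(2, 32) probabilities. Games are skipped at an extra 5%.

What the generator does *not* emulate: clock-time/circadian structure beyond
the morning/afternoon slots, response-time dynamics beyond a trial-mean
press lag, item-specific wording effects, and any feedback from choices to
later states. Passing tests on synthetic data therefore validate the
statistical machinery and its calibration, not the psychological claims on
real data.

# Descriptive and reliability analytics

* `repeated_measures_correlation()`: ANCOVA decomposition (participant
  indicators + one shared slope), df = pairs - participants - 1, Fisher-z CI
  with SE $1/\sqrt{df-1}$. Sleep quality is paired with the same morning's
  motivation only.
* `weekday_analysis()`: one-way ANOVA on participant x weekday means of the
  within-person normalized state (we follow the normalized-state convention
  for this analysis) plus the Monday-Wednesday vs Thursday-Sunday paired t.
* `state_autocorrelation()`: per-person ACF to lag 4 with group mean +- SEM,
  or the within-day mixed model (afternoon ~ morning x trait, random
  person slope, no intercept - person-centering already removes levels).
* `test_retest_icc()`: two-way random-effects, absolute-agreement,
  single-measure ICC for each of the 28 2-game pairs; the variant is not
  dictated by the conventions of the field's reports, so it is recorded in
  the output metadata.
* `practice_effect_comparison()`: plateauing power law $a - b\,t^{-c}$
  ($b,c \ge 0$, bounded least squares; the form plateaus at $a$) against the
  per-person state regression, compared by paired t on $R^2$.
* `fit_state_choice_model()`: lme4/lmerTest mixed models for willingness
  (state x trait + demographics, random intercept + state slope), the
  trial-level logistic model, and press vigor; REML for estimation, ML for
  likelihood-ratio comparisons, Wald CIs, Satterthwaite p-values for linear
  models - conventions recorded here because the source analyses do not state
  them.

# Numerical choices and degenerate inputs

* Willingness is reported in percent (chosen - unchosen effort), bounded in
  [-60, 60] on the 20-80% grid; efforts are stored as fractions internally.
* Constant series: a participant with zero state variance contributes z = 0
  to the weekday analysis (a centered constant), is dropped from ACF
  profiles with a count, and makes rank correlations error explicitly.
* All-success cohorts raise a separation warning instead of a spurious
  slope; catch-only games raise an undefined-summary error.
* HDI ties break to the leftmost window; both behaviors are asserted against
  brute-force enumeration.
* The HMC guard treats non-finite Hamiltonians as rejected divergent
  proposals; divergences during sampling flag the fit.

# Validation harnesses and problem sizes

The test suite validates the pipeline at sizes chosen for a single-CPU
workstation: parameter recovery at 40 participants x 8 games x 24 trials x 3
replicates (prior-drawn ground truth; per-replicate correlations combined on
the Fisher z scale), null-state calibration at 24 participants x 4 games x
100 replicates (90% HDI should exclude zero in ~10%), and the past-vs-future
directionality analysis at 28 participants x 4 games x 20 replicates with a
past coupling of 0.40. The methods scale linearly in participants and games;
study-scale fits (130 x 8 x 24) take a few minutes per chain with the
default settings.

# Known limitations

* The joint model treats occasions as exchangeable given the group means; it
  does not model the AR structure the generator (and real life) has. This
  leaves some errors-in-variables leakage between correlated lagged states
  in the lag comparison (discussed above).
* Sensitivity offsets are independent across games within participant; real
  data plausibly have person-level stability beyond the trait term, which
  the test-retest ICC quantifies but the model does not exploit.
* The generator emits only trial-mean press lags, so vigor analyses on
  synthetic data cannot probe within-trial dynamics.
* Real-data reproduction requires the original deposit; `read_cohort()`
  consumes the documented CSV layout, and the trait factor score is taken
  as given (the questionnaire factor analysis is out of scope).
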