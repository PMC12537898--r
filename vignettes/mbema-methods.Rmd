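---
title: "Model-based control and real-life drinking intentions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based control and real-life drinking intentions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mbema)
```

# The scientific question

People with alcohol use disorder differ widely in how well they translate an
intention ("this week I want to drink less than usual") into actual
consumption. One candidate moderator is the degree of *model-based* (
goal-directed) behavioural control, measurable in the laboratory with a
two-step sequential decision task. `mbema` implements the full computational
chain needed to study this question in simulation: the task environment, the
hybrid model-free/model-based learner and its estimation, two independent
read-outs of model-based control (the mixture weight $\omega$ and a
regression-based MB score), a synthetic generator for year-long
ecological-momentary-assessment (EMA) drinking diaries, and the cross-level
moderation analyses that link the laboratory read-outs to daily drinking.

# The two-step task

Each trial starts in a single first-stage state with two actions. Action $a$
leads to second-stage state $a$ with probability $p_c$ (the *common*
transition, default $p_c = 0.7$) and to the other state otherwise. Each
second-stage state offers two actions paying a nonzero integer number of
points in $\{-5,\dots,-1, 1,\dots,5\}$. Latent payoff values drift across
trials as Gaussian random walks (default step SD 2 points) reflected at the
payoff bounds; the delivered payoff is the latent value rounded to the
nearest allowed integer. Latent values in $(-0.5, 0.5)$ round away from zero
toward their sign and an exact zero falls to $\pm 1$ by a fair coin, because
the payoff set excludes zero. A run comprises 201 trials.

The transition probability and walk SD are conventions of the gamified task
variant; both are configurable in `task_config()`. Payoff sequences are
generated per agent rather than shared, and trial indices are 1-based in
files.

# The hybrid learner

The model-free system learns with SARSA($\lambda$): after a trial
$(a_1, s_2, a_2, r)$,

$$\delta_1 = Q_2(s_2, a_2) - Q_{MF}(a_1), \qquad
  \delta_2 = r - Q_2(s_2, a_2),$$

$$Q_{MF}(a_1) \mathrel{+}= \alpha_1 \delta_1 + \alpha_1 \lambda \delta_2,
  \qquad Q_2(s_2, a_2) \mathrel{+}= \alpha_2 \delta_2.$$

The model-based system evaluates first-stage actions prospectively through
the known transition structure,

$$Q_{MB}(a) = p_c \max_{a'} Q_2(\mathrm{common}(a), a') +
  (1 - p_c) \max_{a'} Q_2(\mathrm{other}(a), a'),$$

and the first-stage policy is a softmax over the mixture
$Q_{net} = \omega\, Q_{MB} + (1 - \omega)\, Q_{MF}$ with inverse temperature
$\beta_1$ and a repetition bonus $\rho$ added to the previously chosen
action; the second stage uses a softmax over $Q_2(s_2, \cdot)$ with
$\beta_2$. $\omega = 1$ is pure model-based, $\omega = 0$ pure model-free
control. All action values start at zero. Because payoffs enter the
likelihood unscaled (up to $\pm 5$), the $\beta$ parameters live on a
smaller numeric scale than in binary-reward variants of the task; fitted
values near 1.5 correspond to strongly value-guided choice.

This is the canonical 7-parameter variant
($\alpha_1, \alpha_2, \lambda, \beta_1, \beta_2, \omega, \rho$); sharing the
learning rate or the temperature across stages is available through
`fit_subject(constraints = ...)` and, with `glance()`'s AIC/BIC, doubles as
the model-comparison set.

## Estimation

`fit_subject()` maximises the posterior per subject (MAP): the negative log
likelihood plus weakly informative priors — Beta(1.1, 1.1) on unit-interval
parameters, Gamma(shape 1.2, rate 0.2) on the temperatures, Normal(0, 1) on
$\rho$ — minimised in unconstrained space (logit/log transforms) with 10
random restarts (Nelder-Mead, relative tolerance $10^{-10}$, followed by a
BFGS polish of the best restart). Per-subject MAP replaces hierarchical
Bayesian sampling to keep desk-scale determinism; the likelihood recursion
runs in compiled code and is checked in the test suite against an
independent plain-R implementation to $10^{-8}$. A positive-definite
numerical Hessian at the optimum is recorded as `hessian_ok`; a subject
whose restarts all fail is flagged, never dropped silently.

## Prediction-error decomposition

`decompose_rpes()` replays a trial sequence and emits two events per trial.
At second-stage onset the model-free error is
$Q_2(s_2, a_2) - Q_{MF}(a_1)$ and the model-based error
$Q_2(s_2, a_2) - Q_{MB}(a_1)$; their difference is the *unique model-based
component*. At the outcome both systems share $r - Q_2(s_2, a_2)$, so the
unique component is identically zero there — a property the tests assert.
Concatenating both event streams reproduces a combined onset regressor for
use as parametric modulators. Haemodynamic convolution and any image-domain
computation are out of scope; regional "model-based signatures" appear in
this package only as simulated subject-level covariates.

## The MB score

As a model-agnostic complement, `build_stay_table()` recodes each trial pair
into stay/switch of the first-stage choice with the previous outcome
(reward/punishment by the sign of the points — payoffs are never zero) and
the previous transition type, both effect-coded $\pm 0.5$.
`fit_stay_glmm()` fits a logistic mixed model with by-subject random slopes
for all within-subject terms (uncorrelated); the outcome-by-transition
interaction indexes model-based behaviour, and the per-subject MB score is
the fixed interaction plus the subject's conditional-mode (shrinkage)
deviation. An optional correction adds the within-subject standardised
trial number as a covariate; the exact form of corrections used in prior
work varies, so this implementation is a documented interpretation. Across
a cohort spanning $\omega \in [0, 1]$ the MB score tracks the generating
weight with Spearman $\rho > 0.8$ (asserted in the tests).

## Recovery experiments

`parameter_recovery()` simulates agents, refits them, and correlates
generating with recovered values per parameter. Recovery experiments are
informative only when the generating values resemble those of real
cohorts, so the default generating distribution
(`sample_generating_params()`) is calibrated in two steps: $\omega \sim$
Beta(2.4, 1.4) matches the published cohort spread (mean 0.63, SD 0.22),
and the temperature distribution Gamma(4, 2.7) matches the moments of
*fitted* temperatures in a simulated cohort whose stay/switch statistics
reproduce the canonical pattern (outcome effect near 0.6,
outcome-by-transition interaction near 1.4 on the log-odds scale). Cohorts
drawn this way recover $\omega$ with Pearson $r$ of roughly 0.7-0.85 at
study scale (67 agents, 201 trials); a generating parameter held constant
yields an explicitly "undefined" correlation rather than an error.

# The synthetic EMA cohort

`simulate_ema_cohort()` emulates the assessment design of a year-long
smartphone study: 67 subjects over up to 359 days, a drinking-intention
item every 8 days with three categories (none / drink no more than usual /
drink less than usual) and a consumption report every 2 days covering each
of the two preceding days. Intention blocks follow a sticky Markov chain
whose stationary distribution (0.45 / 0.30 / 0.25) is preserved for any
persistence value; persistence defaults to 0.4.

Daily grams of ethanol arise from a hurdle process. A logistic model decides
whether the day involves drinking at all; conditional on drinking, the
amount is log-normal on the $\log(g + 1)$ scale — the same scale the
analysis models use, so generator coefficients and analysis coefficients
are directly comparable. Both parts carry fixed effects for the intention
contrasts, the model-based weight and their interactions (optionally the
three simulated regional signatures, drawn jointly with correlation 0.5),
plus subject random effects; the amount part also has random slopes for the
two intention contrasts.

Calibration choices worth recording:

* The drinking-part defaults use published logistic-regression log-odds for
  this design; the amount-part slopes likewise. The amount *intercept*,
  however, is a conditional-on-drinking intercept and must sit higher
  (3.5) than the published marginal intercept (2.37), because the latter
  averages over abstinent days at $\log(0+1) = 0$. With residual SD 0.8 and
  intercept SD 0.8 the cohort lands on the anchor statistics: mean
  consumption near 32 g/day with a heavy right tail, the reduction
  intention active on about a quarter of days, and an intraclass
  correlation for log consumption near 0.16.
* `missingness` (default 0.24) is the target share of *days* lost to
  missing data, matching the observed ~272 valid days of 359. Each stream
  (rating, report) is therefore dropped completely at random with rate
  $1 - \sqrt{1 - 0.24} \approx 0.128$; a day is valid only if both streams
  cover it. Missing-at-random hooks can be built by filtering the returned
  streams before restructuring.
* Subjects share a common start day by default; staggered entry can be
  emulated by trimming the returned streams.

`restructure_ema()` implements the mapping from raw streams to one record
per day: a rating covers its query day plus the following seven days, later
ratings win on the overlapping day, each report contributes grams to the
two days before its query, conflicting duplicate reports raise an error
naming the subject-days, and days lacking either stream are dropped (or
kept flagged). The mapping is order-independent and idempotent, which the
tests assert.

What the generator deliberately does **not** emulate: beverage-type
decomposition into grams, app compliance dynamics, informative missingness,
seasonal or weekday structure, and any serial dependence of consumption
beyond the 8-day intention blocks. Passing tests therefore show that the
analysis chain recovers what this generator encodes — not that real diaries
satisfy its assumptions.

# Moderation analyses

`fit_moderation()` fits, by maximum likelihood, the linear mixed model of
$\log(g + 1)$ — or the logistic mixed model of the drinking indicator
($g > 0$) — with fixed effects for two intention dummies against the
reference "no specific intention" (contrast 1: drink less vs none;
contrast 2: drink no more vs none), the trait covariates, and all
trait-by-intention interactions. The model-based weight enters uncentred
(it is bounded in $[0,1]$); signature and cognitive covariates are
z-standardised. The `int_less:trait` interaction carries the moderation
question. No multiplicity correction is applied across the four
interactions, by design.

Three nested random structures are supported — intercept only; adding
uncorrelated slopes for the two contrasts; adding their correlations — and
`select_random_structure()` chooses the most complex structure that
improves significantly on its simpler neighbour by chi-square likelihood
ratio test. Random-slope terms are written with explicit 0/1 dummy columns
rather than a factor inside `||`, which keeps lme4's uncorrelated-slopes
syntax reliable and the coefficient names readable. Subjects who never
report a category keep their shrunken slope; nobody is excluded listwise.

Inference: $t$ statistics with Wald degrees of freedom
($n_{obs} - p$) for the LMM, $z$ for the GLMM (with odds ratios). Wald
confidence intervals are the default; profile intervals
(`ci_method = "profile"`) match the reference analysis style for single
fits but are too slow for the replicate-level simulations, which is why
they are not the default. On a non-converged fit the random structure is
simplified automatically and flagged; a constant drinking indicator yields
a flagged separation stub rather than an error.

`icc_unconditional()` reports the between-subject share of
$\log(g + 1)$ variance from the intercept-only model (complement: the
within-subject share). `marginal_means()` evaluates the fixed-effects
linear predictor at chosen trait values per category and back-transforms
($e^m - 1$ grams, or a probability), with delta-method standard errors on
the link scale; values outside the observed trait range warn about
extrapolation. The tests check these means against plug-in arithmetic to
$10^{-8}$ and against emmeans. `moderation_diagnostics()` provides a
light influence report (residual QQ data, subject-level leverage) in lieu
of a robust re-estimation backend, which is out of scope.

# Pipeline and reproducibility

`run_pipeline()` chains simulate-task → fit-hybrid → decompose-rpes →
mb-score → simulate-ema → restructure → analyze under one global seed,
writing every stage artifact as CSV/JSON plus a manifest (schema version,
seed, config hash, file list) and a `run.log`. Outputs are byte-identical
across runs with the same config and seed; any stage failure aborts with
the stage named. The YAML keys `task`, `fit`, `ema`, `analysis`, `seed`
configure a run via `run_config()`.

# Problem sizes and numerical choices

The simulation experiments in the test suite use the study-scale design (67
subjects, 201 trials; EMA horizon 359 days) where a criterion is anchored
to it — parameter recovery across three replicate cohorts, 100-replicate
interval coverage of a known cross-level interaction of $-1.0$, a
200-replicate size check of the null, and the variance-ratio check of the
ICC — and smaller cohorts (around 10-40 subjects, 50-500 trials, 48-120
days) for module-level properties. The MB-score monotonicity check uses a
larger cohort (60 subjects spanning $\omega \in [0,1]$, 700 trials,
$\beta = 2.5$) because the rank correlation is attenuated by per-subject
slope noise and is only a fair test of the score where that noise is small
relative to the interaction spread. Other numerical choices: overflow-safe
log-sum-exp softmax everywhere; reflecting boundaries applied repeatedly
for large walk excursions; ties in the second-stage max resolved by value
(the max is unique by value; where an action must be named, the lower
index); optimisation in unconstrained space with parameters clamped away
from exact bounds by $10^{-9}$ before transforming.

# Known limitations

* Per-subject MAP understates the recovery attainable with hierarchical
  pooling; the recovery correlation for $\omega$ is accordingly nearer 0.75
  than to 1.
* The EMA generator's independence assumptions (MCAR missingness,
  trait-independent intentions, no autocorrelation within blocks) make the
  moderation recovery an internal-consistency check, not evidence about
  real diaries.
* Profile confidence intervals are available but not used in replicate
  simulations; coverage statements are based on Wald intervals.
* Robust mixed-model re-estimation and multi-level vector auto-regression
  are out of scope.
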