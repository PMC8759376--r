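---
title: "Models and methods behind acuitykit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acuitykit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acuitykit)
```

acuitykit evaluates the measurement properties of tactile-acuity scores.
This vignette is the package's own account of the models it implements,
the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic-data path does and does not
demonstrate.

## The observer models

**Caliper observer.** The two-point discrimination task is a
two-alternative forced choice ("one point" or "two points") at caliper
separation $d$ mm. `psychometric_observer()` models the probability of a
"two" report as

$$P(\text{two}\mid d) \;=\; \gamma + (1-\gamma-\lambda)\,
  F\!\left(\tfrac{d-\theta}{\sigma}\right),$$

with threshold $\theta$ (mm), slope scale $\sigma$ (mm), guess rate
$\gamma \in [0, 0.5]$ and lapse rate $\lambda \in [0, 0.1]$. $F$ is the
standard logistic CDF. A cumulative normal would serve equally well; the
logistic was chosen for its closed form, and nothing downstream depends on
the family because only the response probabilities enter the simulation.

**Array observer.** The vibrotactile array has twelve nodes in three rows
of four at 32.5 mm centre-to-centre spacing; columns 1–2 sit on the left of
the neck, 3–4 on the right. `itad_observer()` draws localisation responses
over the nodes with probability proportional to a Gaussian confusion
kernel, $\exp(-d_{ij}^2 / 2s^2)$, of the Euclidean distance from the
stimulated node; $s$ (`localisation_spread_mm`) is the single tunable
spatial-precision parameter. As $s \to 0$ responses are perfect; as
$s \to \infty$ they approach chance (1/12).
`calibrate_localisation_spread()` inverts the induced expected
single-trial accuracy by root finding, so observers can be specified on the
interpretable accuracy scale. Orientation responses are simply correct
with probability `orientation_accuracy`, errors uniform over the remaining
available directions — the orientation percept is not modelled spatially.

**Response times** are log-normal per trial: the task gives no mechanism
for RT generation, so this is a modelling convenience chosen because RTs
are positive and right-skewed; the trial-level log-scale SD defaults to
0.25. It reproduces the qualitative right skew seen in real RT
distributions but none of their sequential structure.

## The staircase

`run_staircase()` implements the adaptive procedure: four runs alternating
ascending–descending–ascending–descending, the first ascending from 15 mm
in 5 mm steps, subsequent runs in 2 mm steps. Three consecutive identical
reports ("two" while ascending, "one" while descending) end a run; after
each run, 10 mm is added in the direction of the completed run before the
reversed run begins. The threshold is the arithmetic mean of the four
reversal distances.

Open points were resolved as follows, each exposed or documented:

- **Which trial scores the reversal.** The first of the three criterion
  trials scores it (the separation at which the percept changed); a config
  switch `reversal_rule = "last"` is provided for sensitivity analysis.
- **Counter reset.** Any contrary report resets the consecutive counter —
  standard staircase practice.
- **Run order.** Strict alternation A–D–A–D (two ascending, two
  descending).
- **The 10 mm jump** is applied once, to the last presented separation,
  and only positions the next run's start; it never elicits a response of
  its own.
- **Bounds and termination.** Separations clamp to
  `[floor_mm = 0, ceiling_mm = 100]`. A clamped boundary cannot be stepped
  past, so three consecutive *identical* reports at a boundary also score
  a reversal there; together with the `max_trials` safeguard (default
  400, exceeded → an explicit non-convergence error) this guarantees the
  procedure terminates for any consistent responder.

For a deterministic threshold-$T$ responder the estimate is provably
within `coarse_step + 3 * fine_step` = 11 mm of $T$; the test suite checks
every integer $T$ from 20 to 80 and, for stochastic observers, that the
median estimate sits within one fine step of the truth.

## Session construction and scoring

Localisation plans deliver 72 trials in six series of twelve — each series
a block-randomised permutation of all twelve nodes; orientation plans
deliver 64 trials in four series of sixteen ordered pairs of grid-adjacent
nodes. "Adjacent" is rook adjacency (the equal row/column spacing makes
diagonal neighbours farther, and the response set is directional), so each
trial offers 2–4 direction options depending on the first node's position.
Within a series, trials alternate between left and right side strictly
while both sides have stimuli remaining in the block, relaxing only when
one side is exhausted.

Scores per test: AS $= 100\,\#\text{correct}/\#\text{trials}$; RT $=$ mean
response time; RCS $= \sum\text{correct} / \sum(\text{RT in minutes})$.
The *overall* AS and RT are means of the two per-test values, but the
overall RCS **pools** numerator and denominator over both tests. Pooling
is the only definition consistent with RCS's own arithmetic: the mean of
two per-test RCS values differs from the rate computed on the combined
record whenever the tests differ in duration, and the pooled rate always
lies between the per-test rates (asserted as a property test).

## Reliability statistics

For a complete $n \times k$ subjects-by-columns table the two-way crossed
ANOVA without replication gives $MS_R$, $MS_C$, $MS_E$, and variance
components $\hat\sigma^2_{subject} = (MS_R - MS_E)/k$,
$\hat\sigma^2_{observer} = (MS_C - MS_E)/n$,
$\hat\sigma^2_{residual} = MS_E$. Negative component estimates are
reported as-is and flagged — truncation would hide the sampling behaviour —
but are floored at zero inside the SEM radical (with a warning) so the SEM
is always defined.

$$ICC(2,1) = \frac{MS_R - MS_E}
  {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}, \qquad
  ICC(2,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}.$$

Confidence intervals use the Shrout–Fleiss F-based procedure (the SPSS
convention); the average-measures interval is the Spearman–Brown transform
of the single-measures bounds. $k$ is always the number of columns
actually supplied — 3 assessors in the inter-rater design, 6 or 4 series
in the internal-consistency analyses. The implementation is checked three
ways: closed-form mean squares against explicit sum-of-squares enumeration
on small integer matrices (to 1e-10), variance-component recovery against
the generator, and point estimates/intervals against an independent
implementation on a frozen fixture.

SEM $= \sqrt{\hat\sigma^2_{observer} + \hat\sigma^2_{residual}}$ (the
agreement form: subject variance excluded by construction); CoV
$= 100\,\text{SEM}/|\bar y|$ with bands `<10%`, `10–20%`, `>20%`; SDC
$= z\sqrt{2}\,\text{SEM}$ with two-sided normal quantiles carried at four
decimals (1.2816, 1.4395, 1.6449, 1.9600) to mirror the reporting
convention of clinimetric tables. ICC bands: poor < 0.5 ≤ moderate < 0.75
≤ good < 0.90 ≤ excellent.

## Distribution screens

Bounded scores (the accuracy scores, 0–100%) are screened with the
15%/20% rule: a floor or ceiling effect is flagged when more than 15% of
participants score within the lowest or highest 20% of the scale. Tail
bins are closed intervals, so boundary values count. Response times and
rate scores have no bounded scale (unbounded above, near-impossible
below), so the tail rule is refused for them and only the skewness screen
applies: the adjusted Fisher–Pearson $G_1$ (via `e1071::skewness(type =
2)`, the SPSS default) divided by
$SE = \sqrt{6n(n-1)/\big((n-2)(n+1)(n+3)\big)}$, compared against 1.96 for
$n < 50$ and 3.29 for larger samples.

## Regression and sequential mediation

`ols_enter()` is an ordinary enter-model fit (all predictors
simultaneously) reporting unstandardized $b$, $t$, $p$ and the
semi-partial correlation $sr_j = t_j\sqrt{1-R^2}/\sqrt{df_2}$, whose square
is the predictor's unique $R^2$ contribution (asserted to 1e-8 against
drop-one refits). Two-level factors are coded 0/1 with the first level 0
(so `sex` coded female = 0, male = 1).

`sequential_mediation()` fits the serial two-mediator model with
covariates in every equation:

$$M_1 = i_1 + a_1 X, \quad M_2 = i_2 + a_2 X + d_{21} M_1, \quad
  Y = i_3 + c' X + b_1 M_1 + b_2 M_2,$$

plus the total-effect regression $Y = i_0 + cX$. The indirect effects are
$a_1 b_1$, $a_1 d_{21} b_2$ and $a_2 b_2$; under OLS the decomposition
$c = c' + \sum \text{indirect}$ holds to machine precision on every
dataset, and the suite asserts it at 1e-8. Indirect-effect intervals come
from a case-resampling percentile bootstrap (5000 draws by default, rows
resampled, the three path regressions refit per draw); direct and total
effects carry t-based OLS intervals. $P_m$ = total indirect / total
effect. "Significance" of the total indirect means its bootstrap CI
excludes zero — $P_m$ itself gets no separate test, since it is a ratio of
the two quantities already reported.

Two calibration facts shaped the tests:

- With the $X \to$ mediator paths zero and the mediator $\to Y$ paths
  free, the total indirect effect is exactly zero and its percentile CI
  covers zero at close to the nominal 95%. With *every* path zero the
  indirect estimate is a product of two near-zero coefficients, and
  percentile intervals are known to over-cover severely (coverage near
  99.7%); that regime tests the estimator's conservatism, not its
  calibration. The null-calibration check therefore zeroes the $a$-paths
  only.
- With only $k = 3$ raters, a single ratings matrix carries a 2-df draw of
  rater effects whose noise does not shrink as subjects grow, so a single
  5000 × 3 matrix cannot pin the ICC to ±0.02 (and the single-matrix
  estimator is slightly biased upward by Jensen's inequality). The
  recovery check pools variance-component estimates across replicate
  matrices and forms the ICC from the pooled components, which is
  consistent for the population value.

## What the generators emulate — and what they do not

**Inter-rater design.** `exp1_score_specs()` parameterises ten score
metrics with the observed means, single-measure ICCs and SEMs of the
three-assessor study the package models. Subject variance is backed out
of the ICC identity $\sigma^2_s = \text{SEM}^2\,\text{ICC}/(1-\text{ICC})$;
the error variance $\text{SEM}^2$ is split 25% assessor / 75% residual —
the split is not identified by the published summaries, and a modest
assessor share reflects that trained assessors following a protocol differ
less than trial-to-trial noise. `simulate_ratings()` then draws
$y_{ij} = \mu + p_i + r_j + e_{ij}$ with independent normal components.
Scores are generated directly at the summary level; the rater pipeline
does not re-simulate trial-level sessions.

**Cohort design.** `cohort_spec()` defaults encode the study conditions:
ten participants of each sex in each of five age brackets (18–30, 31–40,
41–50, 51–60, 61–70); latent accuracy linear in age and sex with the
reported coefficients (localisation $b_{age} = -0.20$, $b_{sex} = +8.04$;
orientation $b_{age} = -0.39$, $b_{sex} = +6.69$), intercepts chosen so
cohort means sit near the observed test means, and residual SDs (11% and
13.5%) chosen so the models' explained variance matches the reported
adjusted $R^2$ of roughly 0.14–0.16. Latent accuracies clip at the
forced-choice chance floor (100/12% for twelve-option localisation, 25%
for four-direction orientation) rather than zero. Anthropometry is
coupled to demographics with the observed marginal means (BMI 26.4, neck
surface area 261 cm²) and the qualitative causal pattern age → BMI → neck
surface area ← sex, with magnitudes as free defaults — the scores depend
on anthropometry with coefficient exactly zero, so any mediated
association in the generated data flows only through the demographic
coupling and the mediation truth is known. Each participant's sessions
are then simulated trial by trial, which is what makes the per-series
internal-consistency analysis meaningful: between-subject latent variance
plus within-series binomial noise produce average-measure ICCs in the
observed 0.8–0.9 range without any direct calibration of that statistic.

Passing tests on this path show that the *estimators* recover the
*generators*. They cannot show that real necks behave like the
generators: no skin physiology, no learning or fatigue across series, no
assessor drift, no RT–accuracy coupling beyond what the latent variables
induce, and anthropometry effects fixed at zero by construction. The
package's value on real data is that every statistic it reports is the
standard clinimetric one, computed the standard way.

## Problem sizes and numerics

The test suite runs the designs at their study sizes (40 × 3 ratings;
100-participant cohorts) and scales Monte-Carlo layers to keep the suite
in tens of seconds: 60-seed coefficient recovery, 200-session score
calibration, 500-replicate mediation coverage at 1000 bootstrap draws, and
100 replicate matrices for ICC recovery. The acceptance script uses 5000
bootstrap draws (the analysis default) and finishes in seconds. Degenerate
inputs fail loudly and early: zero-variance matrices (undefined ICC),
incomplete designs, constant samples (undefined skewness), zero mean
(undefined CoV), collinear designs and mediators, empty record sets, and
out-of-scale values each raise a specific error naming the problem.
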