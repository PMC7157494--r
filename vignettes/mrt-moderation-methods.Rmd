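---
title: "Estimating time-varying effect moderation in a weekly micro-randomized trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating time-varying effect moderation in a weekly micro-randomized trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtmod)
```

## The problem

Mobile-health push notifications can help people in stressful work
environments maintain mood, physical activity and sleep — but only if they
arrive at receptive moments. A micro-randomized trial (MRT) answers the
timing question experimentally: every participant is re-randomized at many
decision points, so the causal effect of treatment *at each point* can be
estimated, and its dependence on the participant's recent state (a
*time-varying moderator*) can be tested.

`mrtmod` simulates and analyses a six-month weekly MRT modelled on a large
cohort of first-year medical residents: 1565 participants, 26 weekly
decision points, uniform randomization to mood / activity / sleep
notifications or a no-notification week, and within active weeks an
independent 50% chance of delivery each day (so an active week delivers
3.5 notifications on average — enough to be noticeable, not enough to
cause treatment fatigue). Outcomes are 7-day averages of a daily 1–10 mood
score, daily step count, and nightly sleep minutes.

## The moderation model

All quantities are aggregated to the participant-week. With outcome
$Y_t$, treatment $Z_t$, moderator $M_t$ (the previous week's average of
the same measure) and controls $X_t$, the working model is

$$E(Y_t \mid X_t, M_t, Z_t) = a_0^\top X_t + a_1 M_t + b_0 Z_t + b_1 Z_t M_t.$$

$b_1$ is the quantity of interest: the change in the treatment effect per
unit of the moderator. With four arms, $Z_t$ becomes three centered
indicators (reference: the no-notification week) and $(b_{0k}, b_{1k})$
are per-category; in *binary* mode the three active arms collapse into a
single indicator. Step and sleep analyses operate on the average daily
*square-root* scale, which symmetrizes the heavy right tails; mood stays
on its raw 1–10 scale.

## Weighted-and-centered least squares

Ordinary regression of longitudinal outcomes on treatment interactions is
biased for causal moderation when the nuisance terms ($a_0^\top X_t + a_1
M_t$) are misspecified. The estimator used here centers each treatment
indicator at its known randomization probability, $\tilde Z_{tk} = I(Z_t
= k) - p_k$, and solves weighted least squares; because
$E[\tilde Z_{tk} \mid \text{history}] = 0$ by design, the moderation
coefficients stay (asymptotically) unbiased even under nuisance
misspecification. When the centering probabilities equal the true
randomization probabilities the observation weights are 1; the weight hook
is retained for sensitivity work with mismatched probabilities.

Two algebraic facts pin the implementation and are enforced by tests:

* With a saturated model, the centered coding is a linear
  reparameterization of the ordinary uncentered interaction regression:
  $b_{0k}, b_{1k}$ agree coefficient-for-coefficient, while the intercept
  and moderator main effect absorb $\sum_k p_k b_{0k}$ and
  $\sum_k p_k b_{1k}$.
* The cluster sandwich $B^{-1} M B^{-1}$ with bread
  $B = \sum_i X_i^\top W_i X_i$ and meat
  $M = \sum_i X_i^\top W_i r_i r_i^\top W_i X_i$ halves exactly when every
  cluster is duplicated.

Inference uses the standard normal reference with $\pm 1.96$ CIs — with
1565 participant clusters the small-sample correction is immaterial. A
$t$ reference with clusters-minus-parameters degrees of freedom is
available (`test_coefficient(..., reference = "t")`) for small cohorts; no
small-sample meat correction is applied by default for the same reason.

The weekly design matrix drops rows with a missing outcome, moderator or
control; the rank of the design is checked and a rank-deficiency error
names the collinear columns. Estimates are invariant to row order and
cluster relabeling.

## Aggregation choices

* **Transform, then average.** The weekly step outcome is the average of
  the daily square roots, not the square root of the weekly average; a
  regression test pins the order (for daily values $4,9,16,25,36,49,64$
  the weekly outcome is $5$, not $\sqrt{29} \approx 5.385$).
* **Moderator and controls.** Week $t$ carries the realized week $t-1$
  averages of all three measures; the moderator is the lag of the outcome
  measure, the other two lags plus the participant's pre-study baseline
  average serve as controls (configurable). The WCLS moderation estimate
  does not depend on this set being correct; it only sharpens precision.
* **Week 1** uses the pre-study baseline window as its "previous week".
  Weeks with no observed prior average carry the last available average
  forward (pre-imputation only; after imputation every day exists).
* **Reference category** is the no-notification week; category order is
  activity, sleep, mood.

## The synthetic cohort

The generator is the generative mirror of the analysis model: week-level
means follow $a_0 + a_1 M_{it} + \sum_k (b_{0k} + b_{1k} M_{it}) I(Z_{it} =
k) + u_i + e_{it}$ with $M_{it}$ the *realized* previous-week average, so
the lag-1 moderation structure holds by construction rather than by
approximation. Daily values add independent noise around the weekly mean
and are clipped to the valid range; square-root outcomes are generated on
the root scale and squared back, which guarantees non-negative raw values.
The week-1 moderator is a baseline average drawn from the process's
stationary law given the participant intercept.

Defaults (`ihs_truth()`) were calibrated once so that simulated weekly
averages at $n = 1565$ reproduce the cohort's observed summaries — mood
mean 7.21, SD 1.43; steps 8274 (3285); sleep 6.54 h (1.25 h) — and the
treatment coefficients equal the study-scale estimates (mood moderation
per category $-0.050$ to $-0.053$; steps $-0.039$ on the root scale; sleep
$-0.075$ on the root-minute scale), with intercepts anchored at the
reported effect-curve values (e.g. $+165$ steps at a previous average of
5625). Calibrated noise components (e.g. mood: participant SD 0.65 on the
weekly scale, weekly residual 0.76, daily noise 1.0, persistence $a_1 =
0.5$) were chosen to split the total variance into realistic
between-participant, week-to-week and day-to-day parts.

What the generator does **not** emulate: weekday/weekend and shift-schedule
structure (daily noise is exchangeable within the week), serially
correlated daily noise, floor/ceiling response styles in the mood EMA
beyond rounding and clipping to 1–10, and informative (not-at-random)
missingness. Passing tests therefore demonstrate correctness of the
estimator under the model's assumptions, not robustness to every feature
of real wearable data.

Message streams alternate tip / insight framings within each
participant-category and draw identifiers without replacement from
per-(category, type) buckets of 7, refilled when exhausted; with uniform
category shares and 3.5 deliveries per active week this reproduces a
roughly 16-week interval between repeats of any given message. Note that
an identifier ending one bucket cycle can legally open the next, so the
*minimum* spacing between repeats is not bounded by the bucket size; the
tests assert the exact property (each cycle exhausts the bucket).

## Missingness and imputation

Attrition is missing-at-random by construction: a daily nonresponse
probability and a week-level dropout gate both follow logistic models in
the week index and the previous week's *observed* average (never the
current, unobserved value). Defaults produce survey response that starts
near 85% and declines into the 40–50% range by week 26, wearable wear
somewhat better, and whole-week gaps growing over the study — the
qualitative retention pattern of a long mobile-health cohort.

Missing days are multiply imputed ($M = 20$ by default) with sequential
stochastic regression on the analysis scale: regression parameters are
drawn from their approximate posterior per imputation, then weeks are
filled in order so that imputed week $t$ feeds the week $t+1$ predictor.
Predictors are the previous week's completed average, the baseline
average, week index, day-of-week dummies, and the current week's arm — and,
importantly, the arm-by-previous-average interactions. Omitting those
interactions makes the imputation model uncongenial with the moderation
analysis and visibly attenuates the pooled $\hat b_1$; with them the
pooled estimates track the complete-data fits. Imputed values are clipped
to the valid ranges (and rounded for the integer mood scale); they are
stochastic draws, never conditional means.

Per-coefficient results combine across imputations with the classic
pooling rules: $\bar Q$, within-variance $\bar U$, between-variance $B$,
total $T = \bar U + (1 + 1/M) B$ and degrees of freedom $\nu = (M-1)(1 +
\bar U / ((1 + 1/M) B))^2$; $p$-values and CIs use the $t_\nu$ reference.
The Barnard–Rubin small-sample adjustment is available via `dfcom` but is
not the default — with tens of thousands of participant-weeks the
complete-data degrees of freedom are effectively infinite.

Complete-case analysis of the weekly panel remains consistent here
(selection depends only on history, and randomization is independent of
history) but loses efficiency and uses a noisier observed-days moderator,
which mildly attenuates $\hat b_1$; the imputation stage restores the
full-week moderator.

## Effect curves and retransformation

A fitted category's moderated effect is the line $\delta(m) = \hat b_{0k}
+ \hat b_{1k}\, g(m)$ on the analysis scale, with delta-method pointwise
bands from the joint sandwich covariance. For square-root outcomes the
natural-scale effect anchors the control-condition mean at the moderator's
own value: $(\sqrt m + \delta(\sqrt m))^2 - m$. This anchor makes the
retransformation exactly invertible ($\delta = \sqrt{m + e} - \sqrt m$
recovers a natural effect $e$ to $10^{-9}$) and reproduces the reported
natural-scale effect pairs for both steps and sleep to their printed
rounding. The curve crosses zero exactly where $\delta(\sqrt m)$ does.
One caveat: for a small negative slope the natural-scale curve is only
decreasing above a turnover point ($\approx 2550$ steps for the default
coefficients); within the cohort's observed moderator range it is strictly
decreasing.

Standardized effect sizes divide the natural-scale effect by the cohort SD
of the weekly-average outcome (1.43 points of mood, 3285 steps, 75 min of
sleep), rounded to two decimals for reporting.

## Numerical and reproducibility choices

* All randomness flows from user-supplied integer seeds; each simulation
  stage (randomization, scheduling, messages, outcomes, missingness,
  imputation) uses a decoupled substream derived from the seed and a stage
  label, so regenerating one stage never shifts another. Fixed seeds give
  bit-identical tables.
* Least squares is solved by QR; the sandwich uses per-cluster score sums
  via `rowsum` (no per-cluster loops), and the covariance is symmetrized
  against rounding drift.
* Daily clipping is applied after adding noise and before weekly
  averaging, keeping raw scales valid without materially distorting weekly
  means at the calibrated noise levels.
* CSV panels encode missing values as empty fields; readers validate key
  uniqueness, the day-week relation, delivery-arm consistency and value
  ranges.

## Validation problem sizes

The packaged checks exercise: exact arithmetic identities (centering
values, sandwich halving to $10^{-10}$, pooling hand-arithmetic,
retransformation inversion to $10^{-9}$); operating characteristics at
$n = 300$ participants and 26 weeks — moderation-coefficient recovery
within $|{\rm bias}| < 0.005$ over 300 replicates, and type-I error /
CI coverage over 500 null replicates; and cohort-scale calibration at
$n = 1565$. The estimator-property simulations use the continuous linear
outcome process (without the mood EMA rounding/clipping), because
discretization slightly attenuates the *generative* coefficient — that is
a property of the measurement scale, not of the estimator; the attenuation
at the calibrated noise levels is about 4% and is visible by comparing
discretized and continuous fits on the same assignments.

## Limitations

* The weekly working model is linear in the moderator; curvature in the
  true moderation (e.g. effects flattening at high moderator values)
  is not represented.
* The sandwich assumes independent participants; shared environments
  (hospitals, programs) that induce cross-participant correlation are not
  modelled.
* The imputation model is a pragmatic sequential-regression stand-in whose
  contract (daily level, treatment-aware, longitudinal) is tested, but it
  is not a full joint model of the three measures; cross-measure
  imputation borrowing is limited to the lagged controls.
* Simulated attrition is missing-at-random by construction; sensitivity to
  not-at-random mechanisms is out of scope.
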