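---
title: "Models and methods: simulating and fitting exercise reward valuation"
author: "exertvalue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: simulating and fitting exercise reward valuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exertvalue)
```

## The scientific problem

Sedentary people tend to self-select low exercise intensities, and future
exercise is devalued ("discounted") steeply, much like food and unlike
money. `exertvalue` implements, as one testable pipeline, the
computational machinery of a study design that tries to shift this
valuation by evaluative conditioning: elevated heart rate during interval
training (the conditioned stimulus) is paired with a sweet oral solution
(the unconditioned stimulus), delivered by a dual syringe pump whose
sweet fraction is driven by live heart rate. Around that controller sit
the behavioural assays — an adjusting-amount delay-discounting task over
three commodities, hyperbolic (Mazur) discounting fits with an exclusion
rule, and a shared-k hyperbolic effort-valuation model — plus a synthetic
cohort generator that provides ground truth, so that every stage can be
validated by parameter recovery without any raw study data.

## The conditioning controller

Two pumps share a fixed combined flow of `totalRate` = 2 ml/min (within
the normal range of stimulated saliva flow). With baseline heart rate
$HR_0$ (the rate at the participant's self-selected speed) and
age-predicted maximum $HR_{max} = 220 - age$, the sweet fraction of the
flow is quadratic in the elevation above baseline:

$$ sweet(HR) \;=\; total \cdot
   \frac{(HR - HR_0)^2}{(0.85\,HR_{max} - HR_0)^2}, $$

clamped to 0 at or below baseline and to the full flow at or above
$0.85\,HR_{max}$. The clamping is our choice: the law is only stated
between its endpoints (0% sweetness at baseline, 100% at the 85%
threshold), and clamping is the only physically realisable extension (no
negative or super-total flows). The source prose also once states the
threshold condition with the opposite inequality sign; we follow the
equation and its endpoint anchors, under which sweetness increases with
heart rate. One session ramps through six two-minute holds at 60–85% of
$HR_{max}$ in 5% steps (ramps ~10 s, 90 s baseline recovery between
cycles), and six pairing events are logged per session: three sessions a
week for three weeks gives the canonical 54 pairings.

The heart-rate trace in `simulate_session()` is a first-order relaxation
toward the schedule's momentary target, $\dot{HR} = (target - HR)/\tau$,
with $\tau$ = 30 s by default — typical cardio-acceleration kinetics —
plus optional Gaussian sample noise at the 1 Hz command cadence of
consumer HR monitors. Both constants are configurable because no kinetics
are prescribed by the design; nothing downstream depends on them beyond
the pairing-event bookkeeping.

## Delay discounting: task and fit

Subjective value of a delayed reward follows Mazur's hyperbola
$V = A/(1 + kD)$ with delay $D$ in days and a per-day constant $k$. The
computerised task offers fixed commodity menus — money
£2–£50 in eleven steps, food 5–150 bites, exercise 5–150 minutes (one
"gym session" being 30 minutes) — at delays of 0 ("end of this
session"), 1, 7, 30, 60 and 180 days. Delay 0 only frames the immediate
option and is never fitted.

The published task description names "IP criteria" without details, so
`run_adjusting_task()` implements the standard adjusting-amount
realisation as a bisection staircase: the delayed option is anchored at
the largest menu reward $A$; the immediate offer is the midpoint of a
bracket on $[0, A]$, which each choice halves; the staircase stops when
the bracket is narrower than one menu step and the indifference point
(IP) is the final midpoint. This realisation is oracle-testable: for any
noise-free hyperbolic responder the recovered IP is provably within one
step of $A/(1+kD)$, which the test suite asserts at every delay.
Staircases for different delays are interleaved in seeded random order,
and distractor trials — verbatim repeats of earlier offers that never
update a bracket — are interspersed at a default 15% rate (the design
mentions distractors but no rate). Non-convergence within the trial
budget flags the curve rather than failing silently.

`fit_hyperbolic()` minimises $\sum_D (IP_D/A - 1/(1+kD))^2$ over
$k \ge 0$. Normalising by $A$ puts the three commodities' different units
on one scale (whether the original analysis fitted raw or normalised IPs
is unstated; the convention is recorded in the fit object as
`normalised`). The one-dimensional objective can be nearly flat at the
extremes, so the optimiser is a multi-start bounded scalar minimisation:
a log-spaced candidate grid from $10^{-6}$ to 10 (plus $k = 0$) followed
by local refinement, and the tests compare it against an independent
dense grid-search oracle. $R^2$ is computed on the normalised points
about their mean — the standard definition, none being stated. A curve
whose points are all equal has zero total sum of squares; its $R^2$ is
reported as `NA` and inclusion is decided by whether the $k=0$ hyperbola
fits exactly (all points at $A$). Otherwise `apply_exclusion()` removes
fits with $R^2 < 0.7$, strictly: a fit at exactly 0.7 is retained.
Before parametric group statistics, `transform_for_stats()` applies the
study's transforms — natural log for the right-skewed $k$ (the log base
is immaterial to rank-based and linear-model conclusions and is recorded
in the output), squaring for perceived exertion.

## Effort valuation: the shared-k model

The effort model values a self-paced exercise bout as
$V_p = M/(1 + kC)$: pleasantness as subjective value, perceived exertion
as cost. Observables map onto the model as

* $V_p$ = Feeling Scale rating / 5. The division by the scale maximum
  (rather than an affine $[-5,5]\to[0,1]$ rescale) is forced by the
  published tables: pooled group FS means of 4.27 (baseline) and 4.335
  (post-training) reproduce the published normalised values 0.854 and
  0.867 exactly under $FS/5$. Negative ratings map to negative value,
  which is permitted — displeasure is a negative subjective value. (The
  analogous follow-up value printed as 0.949 is *not* reproducible from
  the printed group means under this rule; we record the discrepancy and
  assert nothing about it.)
* $C$ = raw Borg RPE (6–20), untransformed in the model.
* $M$ = reward value from fitness: heart rate per km/h of speed is an
  inverse fitness index, and the default mapping is
  $M = \mathrm{ref}/\mathrm{hrPerSpeed} + \Delta M$ with the cohort
  baseline mean as reference — fitter participants perceive a larger
  reward, and a conditioned reward adds on top. The exact mapping used in
  the original fits is unrecoverable, so it is a named, swappable
  strategy recorded in fit metadata, and the published per-condition
  constants (0.204, 0.204, 0.212, 0.126, 0.042) are treated as
  qualitative anchors rather than exact targets.

`fit_shared_k()` fits one $k$ per condition label (time point × group)
by the same multi-start bounded least squares, and compares predicted to
measured $V_p$ with an exact two-sided sign test (binomial tail doubling,
identical to full enumeration of sign patterns; zeros dropped and
reported). Because the phrase "Wilcoxon sign test" is ambiguous between
the sign test and the signed-rank test, the signed-rank statistic is
reported alongside for $n \le 25$.

The model's key qualitative prediction — the reason the COTR follow-up
constant collapses — is a confound direction: if the data contain a
reward surplus $\Delta M$ the fitter does not model, the only way the
hyperbola can reach the observed (higher) values is to shrink the cost
term, so the fitted $k$ decreases. On noise-free synthetic cohorts the
fitted $\hat k$ is strictly decreasing over
$\Delta M \in \{0, 0.1, \dots, 0.5\}$, and the test suite asserts both
this and exact recovery ($\hat k = 0.204$) at $\Delta M = 0$.

## The synthetic cohort generator

`make_cohort()` draws latent profiles for the three arms (10/24/24 in a
58-participant default, mirroring the study's completers). Discount
constants are log-normal — delay-discounting constants are strongly
right-skewed, which is also why the study log-transforms them — centred
on the published commodity medians (money 0.02, exercise 0.17, food
0.25 per day). Fitness is Gaussian: 22.1 ± 2.6 bpm per km/h at baseline,
a training gain of 9 ± 3% in the trained arms (zero in NTR), and 80 ±
10% of that gain lost again by the 4-week follow-up. The conditioned
reward increment $\Delta M$ = 0.2 applies to the COTR arm only at
follow-up. The joint distribution of latent traits is not stated
anywhere; these defaults are conventions chosen once, not claims about
the study sample.

Selected intensity emerges from the effort model rather than being drawn
directly: `simulate_trial_record()` picks the speed maximising

$$ V_p(s) \;=\; \frac{\kappa \, \frac{\mathrm{ref}}{\mathrm{hrPerSpeed}}
   \,(s/s_{ref})^{\gamma} \;+\; \Delta M \, q(HR(s))}
   {1 + k_{effort}\, C(s)} $$

over a 0.1 km/h grid on 3–16 km/h (treadmill walking-to-running range).
Three modelling choices deserve justification:

* **Speed-dependent reward.** With a reward constant in speed the
  hyperbola is strictly decreasing in cost, the argmax degenerates to
  the slowest grid speed, and training could never raise selected speed.
  The reward therefore grows with accomplished intensity with
  diminishing returns, $(s/s_{ref})^{\gamma}$, $\gamma = 0.715 < 1$,
  which yields an interior optimum $s^* \propto 1/(k \cdot
  \mathrm{hrPerSpeed})$ — training (lower hrPerSpeed) raises the
  optimum, as observed. At any fixed speed the reward reduces to the
  same fitness ratio the effort fitter uses.
* **Latent cost unclamped above the scale top.** Expected RPE is affine
  in the heart-rate fraction between rest (60 bpm) and maximum,
  $C = 6 + 14\,(HR - 60)/(HR_{max} - 60)$, clamped below at 6. The
  *latent* cost is deliberately not clamped above 20: an upper clamp
  would make supra-maximal speeds the cheapest per unit reward and the
  argmax would jump to the grid maximum. Observed RPE is clipped to its
  6–20 scale at recording time, as are Feeling Scale ratings to −5..+5.
* **Conditioned reward follows the US-delivery profile.** The learned
  increment enters as $\Delta M \, q(HR)$ where $q$ is the same clamped
  quadratic the controller uses to deliver sweetness — the conditioned
  reward is strongest at the heart rates where pairing actually
  happened, and saturates at the 85% threshold. This makes selected
  speed non-decreasing in $\Delta M$ (asserted property) while the
  effort *fitter* still sees only the unmodelled surplus, reproducing
  the k-collapse direction end to end.

Baseline heart rate is not an independent draw: it is by definition the
heart rate at the self-selected baseline speed, so it is derived from
each profile's own noise-free baseline optimum (the conditioned term is
inactive at baseline, so this is not circular), capped below the
controller's saturation threshold.

The scale constant $\kappa$ = 2.8 and $\gamma$ = 0.715 were calibrated
once, by Monte-Carlo over seeded cohorts, to the published baseline
conditions — preferred speed 5.25 ± 1.27 km/h with Feeling Scale means
near 4.3 (implying model $V_p$ near 0.85, consistent with the published
reward magnitudes) — and then frozen; the calibration is itself asserted
by a 2-standard-error test. Choices in the simulated task use the
hyperbolic values with logistic noise (temperature `choiceNoise`, default
0.05 in commodity units; zero gives the exact argmax with a seeded fair
coin at exact ties, avoiding order bias).

What the generator deliberately does **not** emulate: sex differences,
questionnaire scores, body composition, time-varying delay-discounting
constants (each profile's $k$s are fixed truths; observed change across
time points in real data would appear here only through task noise), and
any dependence of choice noise on commodity. Passing recovery tests
therefore show that the estimators are consistent and unbiased under the
model's own assumptions — not that real cohorts satisfy those
assumptions.

## Numerical choices and degenerate inputs

* Optimiser: `stats::optimize` on a bracket around the best of a
  log-spaced multi-start grid; tolerance $10^{-10}$; $k = 0$ always kept
  as a candidate. Tests hold it to $10^{-3}$ of a dense grid oracle and
  to $10^{-6}$ on exact data.
* Quantiles in summaries: linear interpolation between order statistics
  (type 7), SD with the $n-1$ denominator; both recorded choices, since
  the published tables state no convention. Single-observation groups
  report `NA` SD; empty groups are dropped with a warning.
* Degenerate discounting curves (all points equal) and flat effort
  objectives (all costs and rewards equal) are flagged, never silently
  fitted.
* Exact ties in deterministic choice are broken by a seeded fair coin.
* Every seeded generator saves and restores the caller's RNG state, so
  results are pure functions of (inputs, seed); the pipeline derives
  per-participant sub-seeds arithmetically and keeps them within the
  32-bit integer range.

## Problem sizes

The validation suite uses the sizes the analyses themselves suggest:
recovery at $n = 200$ per commodity for discounting medians, 100 noisy
curves for oracle agreement, 48-observation conditions for the effort
fit (the study's pooled-arm size), and full 58-participant pipeline runs
for determinism checks. A complete pipeline run — cohort, conditioning
sessions, three-commodity tasks at all assessed time points, all fits
and summaries — takes a few seconds.

## Known limitations

* The staircase is a faithful-but-not-verbatim reconstruction of the
  original computerised task, whose exact trial-generation rules live in
  unpublished scripts; only its convergence contract (one step from the
  hyperbola for a consistent responder) is guaranteed.
* The effort model's $M$ mapping is one defensible choice among several;
  fitted $k$ magnitudes depend on it, which is exactly why published
  constants are anchors for direction and stability, not equality
  targets.
* The heart-rate dynamics are first-order and ignore drift, thermal
  strain and day effects; they are adequate for pairing accounting, not
  for physiological inference.
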