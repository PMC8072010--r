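---
title: "Methods: analyzing virtual-navigation foraging behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing virtual-navigation foraging behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rowforage)
```

## The task and what the pipeline measures

In Restaurant-Row-style foraging tasks, a subject circles a square track
with four reward sites, one per reward category (video categories in the
movie variant, candies in the food variant). On entering a site's *offer
zone* they see an offer: this category's reward, available after a delay
drawn from 3–29 s without replacement within category. They can **stay**
(walk to a platform and wait out the delay), **skip** (move on), or, after
starting the delay, **quit**. Because time is the only currency, the
willingness to wait for a given category defines an economic threshold, and
the moments spent deciding expose deliberation.

`rowforage` implements the full behavioral pipeline for such sessions:

* per-category **delay thresholds** by a padded leave-one-out Heaviside fit,
  with response-pattern classification;
* **offer-zone VTE metrics** — decision latency, reaction time, integrated
  distance, total rotation (the navigation analogue of the rodent IdPhi
  measure), rotation reversals, pausing, entry bias — with the task's
  exclusion and normalization rules;
* **economic context labels** — regret-inducing vs control conditions,
  choice-sequence cells, preference overrides — and paired contrasts;
* **sunk-cost analyses** — conditional delay-completion curves, and a
  logistic model of the entry-bias effect on choice;
* **delay-discounting survey scoring** (hyperbolic k by response
  consistency);
* a **synthetic-agent simulator** whose ground truth makes every estimator
  testable by parameter recovery, with no data download.

## Delay thresholds

Choices are coded stay = 1, skip/quit = 0 (a quit is a late rejection of
the delay). For one participant and category the series is *padded* with
one synthetic stay at 1 s below the minimum offered delay and one synthetic
skip at 1 s above the maximum, so all-accept and all-reject series still
admit a step fit; synthetic points are flagged and never used as real
trials.

The Heaviside fit finds the threshold minimizing the count of
misclassified points under "stay iff delay < threshold". Since the error is
piecewise constant, candidate thresholds are the midpoints between
consecutive sorted unique delays; ties are resolved by the mean of all
minimizing candidates (symmetric and deterministic — note that when ties
span disjoint regions the mean can fall between them, which is inherent to
this tie-break). Each trial's threshold comes from a leave-one-out subfit
on the other offers of the same category, re-padded within the subset so
every subfit is self-contained; the participant's overall threshold is the
arithmetic mean of trial-specific thresholds.

An *inverse* fit repeats the procedure on the inverted choices (inverted
first, then padded). Classification uses the mean leave-one-out errors:
`normal` when the forward error is smaller, `long_delay_pref` when larger,
and on ties `full_stay` / `full_skip` when at least 75% of offers were
accepted / skipped, otherwise `unclassified`. Offer **value** is
threshold − delay (positive = better than threshold; value 0 is the
maximally difficult offer); values are only defined for `normal`
categories, and boundary trials are excluded from deviation coding in the
choice models.

## Offer-zone metrics and normalization

All measures are sample-wise and rate-agnostic, because the log sampling
rate is not fixed by the protocol. Heading differences are wrapped to the
minimal angle in (−180°, 180°]; any other convention inflates rotation at
the 0/360 seam. Reversals count sign changes among wrapped increments of at
least 1° (configurable) — raw sign changes over-count on noisy logs.
Pausing sums inter-sample intervals with displacement below 10⁻⁶ track
units and heading change below the same 1° jitter — an exact-equality
reading with float tolerance. Entry bias is the entry position scaled to
hallway width, −50% at the reward-side wall to +50% at the exit-side wall.

Exclusions follow the task's rules with their different scopes: decision
latencies above 15 s (strict) remove the trial from *all* offer-zone
measures; rotation above 360° (strict) removes *only* the rotation
measures; reaction times above 15 s are excluded from the reaction measure.
Exclusion tallies are logged by the pipeline so the filters are auditable.

Retained values are log10-transformed (a strong positive skew is expected
for times, distances and rotations) then z-scored within session; zeros are
offset to half the smallest positive retained value before the log;
zero-variance sessions give all-zero z with a warning; reversal counts are
never normalized. Normalizing within session is the mechanism that removes
stable between-subject differences (age, gender, gaming experience);
covariates are carried alongside for stratified summaries, and full
covariate regression is out of scope.

**Value tuning.** Deliberation predicts that z-latency and z-rotation peak
where value approaches 0. `value_tuning()` bins values in 2-s bins (one bin
centered on 0), computes per-participant bin means (at least 3 trials per
bin, at least 10 value-labeled trials per participant) and a
per-participant OLS slope of z on |value|; the cohort summary is the mean
slope with a t-based confidence interval. `tuning_peak()` reports the bin
with the maximal cohort mean among bins supported by a minimum number of
participants (default 5), which guards the argmax against sparsely
populated extreme-value bins.

## Context labels and contrasts

The track is unidirectional, so the previous zone is the immediately
preceding trial. With the current offer poor (above threshold):
skipping/quitting a good previous offer makes the trial *regret-inducing*;
having accepted a good previous offer, *control-1*; having skipped/quit a
poor previous offer, *control-2*. Sequence cells are (decision on i−1,
decision on i) with quits grouped with skips (configurable). Trials whose
own or previous value is unavailable are labeled `none`/`undefined`, never
imputed. Contrasts use participant-level cell means and a Wilcoxon
signed-rank test across participants (normal approximation, so the null
p-value distribution is effectively continuous), dropping participants
missing either cell.

## Sunk costs

**Completion curves.** For investment T, trials that started the delay and
waited at least T seconds (with more than T on offer) are selected;
completion probability is tabulated against integer remaining time and a
weighted least-squares line (weights = trial counts) summarizes it. The
sunk-cost signature is a flattening slope with growing T. Two numerical
choices matter:

* *Common remaining window.* At low investments the curve extends to long
  remainders where it is flat, which mechanically shrinks the fitted slope
  regardless of the hazard — comparing slopes across investments on their
  full, different ranges confounds hazard decay with range.
  `remaining_max` restricts all investments to a shared support (the
  sunk-cost comparisons here use ≤ 19 s, the window common to investments
  0/5/10 under 1–29 s offers).
* *Joint bootstrap.* Confidence intervals come from a participant-level
  bootstrap (percentile, 2,000 resamples by default, seeded). Because the
  investment levels share trials, the package draws one set of resamples
  for all levels and reports `slope_diffs` — pairwise slope differences
  with CIs from the shared resamples. Asking whether two investments'
  slopes differ must use this difference CI; comparing separate per-slope
  CIs ignores the overlap and miscalibrates.

Counts are conserved by construction: trials entering investment T equal
completions plus quits after T.

**Entry bias as a sunk cost.** Where participants enter the offer-zone
hallway is decided before the offer is revealed, so a lateral bias is an
irrecoverable effort investment (≈1.25 s to cross the full width, against a
median decision latency of a few seconds). The model is a logistic
regression of choice (stay = 1) on deviation-coded value type (−0.5 good /
+0.5 poor), continuous entry bias (fraction of width), their interaction,
optional gender terms, and per-participant fixed intercepts — a deliberate
simplification of the study-style Bayesian mixed model: the estimand is the
sign and scale of the bias effect, not literal coefficient reproduction.
Separated participants (all-stay or all-skip) get their intercepts clamped
by two half-success pseudo-observations of small weight, with a warning.
`bias_effect_summary()` converts coefficients into the quantities of
interest: the predicted change in poor-offer acceptance for a 25% reward-
side entry and in good-offer skipping for a 25% exit-side entry, averaged
over participant intercepts.

## Discounting surveys

Each item implies an indifference rate `(delayed/immediate − 1)/delay`
under hyperbolic discounting `V = A/(1 + kD)`. Scoring scans candidate
rates — geometric midpoints of the sorted implied-k ladder plus outer
bounds one geometric half-step beyond the extremes — and assigns the
geometric mean of the consistency-maximizing candidates; consistency is the
fraction of responses matching "choose delayed iff implied k > candidate".
Per-magnitude bins are scored the same way within bin, and the magnitude
effect is reported as per-bin log10 k contrasts. The shipped 21- and
27-item banks are synthetic stand-ins (so labelled) with the structure of
the standard instruments — three magnitude bins over a log-spaced ladder
from ~2·10⁻⁴ to ~0.25 per day; they are plain CSV config files meant to be
replaced by the instrument actually administered.

## The synthetic agent

The generator emulates the statistical structure the analyses assume, not
cognitive mechanism. Choices: `P(stay) = logistic((θ_c − delay)/τ −
β·entry)`; τ = 0 is the deterministic limit (value ties resolve to skip,
and the bias term vanishes). Response styles reverse the value sign or
force full-stay/full-skip. Trajectories are piecewise-linear passes from
the entry position to the chosen exit at the task's travel speed (1.25 s
per hallway width), sampled at 20 Hz, with `Poisson(g(|value|))`
reorientation episodes (heading excursion out and back at 150°/s, optional
200–800 ms stop) inserted at random points, where `g(v) = gain·exp(−v /
width)` uses the agent's *true* threshold. Quits apply a per-second hazard
`h(t) = h₀/(1 + s·t)` in 1-s steps of invested time; `s = 0` is memoryless
(geometric survival), `s > 0` sunk-cost-sensitive.

Defaults are chosen to look like the human data: heterogeneous thresholds
(10/14/19/24 s), τ = 1 s, entry-position SD 10% of width (truncated to the
hallway), bias coefficient 2 (≈5 pp more poor offers accepted at a 25%
reward-side entry), deliberation gain 1 with width 3 s (occasional VTE),
quit hazard 0.002/s with strength 1 (under 1% of started delays quit — the
striking rarity of quitting in humans). Cohorts draw per-participant
parameters from a prior (default: per-category thresholds uniform on
6–26 s) under counter-based child seeds, so enlarging a cohort never
changes earlier participants, and covariate effects can plant subgroup
differences for recovery tests.

What the generator does *not* emulate: learning or trial-order effects,
position/heading log noise (jitter parameters exist but default to clean
kinematics), gaze, re-entries, and any regret-specific mechanism — context
effects in simulated data arise only through value tuning. Passing
recovery tests therefore demonstrates estimator correctness under the
assumed structure, not robustness to every artifact of real logs.

## Recovery experiments: designs and problem sizes

The test-suite recovery experiments fix their designs as follows.

* **Threshold recovery.** 200 noiseless step agents with θ ~ U(4, 28) per
  category on the full 3–29 s sweep; recovery within 1 s (the delay grid
  resolution). With τ = 1 s noise the mean bias stays within ±0.5 s.
* **Deliberation-peak recovery.** 100 replicate 50-agent cohorts, 56
  trials each, with a sharpened VTE condition (gain 3, width 1.2 s,
  episode excursions 30–60°, τ = 0.75): sharp enough that peak-bin
  localization tests the estimator rather than statistical power, and
  small enough excursions that the 360° filter rarely censors the peak
  trials. Null cohorts (gain 0) check that the slope CI covers zero at its
  nominal rate.
* **Sunk-cost ordering.** The 10,000-trial sunk-cost run uses h₀ = 0.16,
  s = 0.75 over 1–29 s offers with the common ≤ 19 s remaining window —
  the design that maximizes the expected slope-gap-to-noise ratio within
  the hazard family (an analytic power calculation from the geometric
  survival model). The memoryless calibration uses h₀ = 0.05 and the
  slope-difference CI described above.
* **Entry-bias recovery.** A two-delay probe design: delays fixed at
  θ ± 5 s. Under the binary value-type coding of the choice model, a full
  delay ladder makes the value term misspecified and attenuates the bias
  coefficient (omitted-covariate attenuation), which would confound the
  recovery check; with two delays the deviation-coded term is exactly
  correct and the estimator is consistent. Null runs use the probe at 120
  trials/participant — with much shorter sessions the fixed-intercept
  Wald intervals undercover (an incidental-parameters small-sample
  effect).

These sizes keep the full suite within a desktop-scale run while leaving
each check comfortable statistical margin.

## Reproducibility and outputs

Every stochastic step derives its stream from one master seed via
counter-based splitting, and `generate_session()` is deterministic given
its seed whether or not trajectories are materialized. The pipeline
(`run_pipeline()`) writes each stage's table as TSV with a provenance
header (package version + configuration hash) and a run log with exclusion
tallies; identical configuration and seed give byte-identical tables. A
thin command-line wrapper (`inst/cli/rowforage.R`) exposes the stages as
subcommands for shell use.

## Known limitations

* The Heaviside threshold is resolved only to the spacing of offered
  delays; with integer delays, recovered thresholds sit at half-integers.
* Pattern classification near the 75% boundary is sensitive to single
  trials in short sessions, as the rule intends.
* The entry-bias model's binary value coding attenuates the bias
  coefficient whenever within-type value variation drives choice (see the
  probe-design note above); for real data the coefficient should be read
  as a sign-and-scale summary.
* Pooled completion curves weight participants by trial counts; the
  `participant_mean` aggregation is available where equal weighting is
  preferred.
* Survey k is interval-identified by the item ladder; recovered values are
  bracketed by adjacent implied rates, not point estimates.
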