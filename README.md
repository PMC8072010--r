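# rowforage

Behavioral analysis of human virtual-navigation foraging tasks
(Restaurant-Row-style "Movie Row" / "Candy Row" paradigms), for researchers
studying deliberation, sunk costs and delay discounting from trial-level
session logs.

In these tasks a participant circles a track with four reward sites; at
each site an offer (reward category + delay of 3–29 s) appears in an *offer
zone*, where the participant stays, skips, or — after starting the delay —
quits. The package turns raw logs (trial tables, offer-zone trajectory
samples, magazine beam-breaks) into the paradigm's standard measures:

- **Delay thresholds** θ per reward category: stay/skip choices, coded
  stay = 1 / skip-or-quit = 0, padded with one synthetic stay at 1 s below
  and one synthetic skip at 1 s above the offered range, then fit with a
  Heaviside step (stay iff delay < θ) by misclassification count, with a
  leave-one-out threshold per trial and classification into normal /
  long-delay-preference / full-stay / full-skip / unclassified response
  patterns. Offer **value** = θ − delay; value ≈ 0 marks the hardest
  decisions.
- **Vicarious trial-and-error (VTE) metrics** in the offer zone: decision
  latency, reaction time, path distance, total rotation Σ|Δheading|
  (the navigation analogue of rodent IdPhi), rotation reversals, pausing,
  and entry bias (−50%…+50% of hallway width), with the paradigm's
  exclusion rules (15-s latency cut removes the trial; >360° rotation
  removes only rotation measures) and log10 + within-session z
  normalization.
- **Context labels**: regret-inducing trials (a poor offer right after
  rejecting a good one) vs the two control conditions, sequential-choice
  cells, preference overrides; paired Wilcoxon contrasts.
- **Sunk-cost analyses**: P(complete remainder | time invested, time
  remaining) curves with bootstrap slope CIs, and a logistic model of
  choice on value type × entry bias with participant intercepts —
  acceptance of `V = A/(1 + kD)`-style waiting costs shaped by effort
  already sunk.
- **Delay-discounting surveys**: Kirby-style consistency scoring of 21-
  and 27-item banks into hyperbolic rates k, overall and per magnitude
  bin.
- A **synthetic-agent simulator** with known ground truth (thresholds,
  choice noise, near-threshold VTE boost, entry-bias effects, quit
  hazards with sunk-cost decay), so every estimator is validated by
  parameter recovery — no data download needed.

## Worked example

```r
library(rowforage)

session <- generate_session(agent_config(thresholds = c(8, 13, 19, 24)),
                            task_config(), seed = 42)
fit <- fit_thresholds(session)
fit$summary
#> # A tibble: 4 × 8
#>   participant_id category   n_trials overall_threshold forward_error inverse_error
#> 1 S001           kittens          27              6.60         1.89           4.81
#> 2 S001           accidents        27             13.5          0             10.6
#> 3 S001           dancing          27             18.5          2.85          12.5
#> 4 S001           landscapes       27             23.5          0.926          5.78
```

The agent's true thresholds were 8/13/19/24 s; each recovered overall
threshold (the mean of leave-one-out trial thresholds) lands within the
delay grid's resolution, and the forward step fit beats the inverse fit
everywhere, so all four categories classify as `normal`.

```r
metrics <- offer_zone_metrics(session)
metrics[1:3, c("trial_index", "offered_delay", "decision", "latency_ms",
               "rotation_deg", "n_reversals", "pause_ms", "entry_bias_pct")]
#>   trial_index offered_delay decision latency_ms rotation_deg n_reversals pause_ms entry_bias_pct
#> 1           0            19 skip           1636         25.6           0      600            2.0
#> 2           1             5 stay           1587         20.8           0      450          -12.1
#> 3           2            22 skip           1630         25.1           0      600            3.1
```

Latency is ms in the offer zone, rotation the summed absolute heading
change in degrees, entry bias the lateral entry position (negative =
toward the reward side). `value_tuning(metrics, "z_latency")` then tests
the deliberation signature: z-latency peaking where value approaches 0.

```r
cohort <- generate_cohort(20, seed = 7,
  prior = list(response_style = "full_stay", quit_hazard_base = 0.1,
               sunk_cost_strength = 2, deliberation_gain = 0),
  include_trajectories = FALSE)
trials <- do.call(rbind, lapply(cohort, function(s)
  transform(s$trials, participant_id = s$participant_id)))
completion_curves(trials, investments = c(0, 5, 10),
                  bootstrap = 500, seed = 1)$slopes
#>   invested    slope    ci_lo      ci_hi n_trials
#> 1        0 -0.00428 -0.00685 -0.00163      2160
#> 2        5 -0.00178 -0.00341 -0.0000944    1556
#> 3       10 -0.00289 -0.00483 -0.000934     1175
```

For this sunk-cost-sensitive quitter the completion-probability slope is
steepest with nothing invested and flattens once time has been sunk (use
`remaining_max` for slope comparisons on a common remaining-time window;
`slope_diffs` carries the difference CIs).

```r
items <- load_item_bank("mcq21")
score_survey(generate_survey_responses(0.015, items), items)
#> <discounting_result> k = 0.017502 (log10 k = -1.757), consistency 1.00, 21 items
```

The simulated discounter's k = 0.015 is recovered inside the bracket of
adjacent item-implied rates, with perfect response consistency.

`run_pipeline(row_config(out_dir = "out", n_participants = 50, seed = 1))`
chains all stages (simulate or read → thresholds → metrics → context →
sunk cost → discounting) into TSV tables with provenance headers and an
auditable run log; `inst/cli/rowforage.R` wraps the stages as shell
subcommands. See the methods vignette
(`vignettes/foraging-analysis-methods.Rmd`) for the models, parameter
choices and recovery-experiment designs, and `inst/extdata/SCHEMA.md` for
the session file formats.

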