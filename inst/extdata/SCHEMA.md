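# Session bundle schema

All timestamps are **integer milliseconds from session start**; delays and
waited times are **seconds**; positions are arbitrary track units. Trial
indices are 0-based and contiguous; zones are numbered 0-3 clockwise around
the track.

## csv_bundle (directory with four CSV files)

### sessions.csv — one row per session
| column | type | meaning |
|---|---|---|
| participant_id | chr | unique key joining the other files |
| task_variant | chr | `movie` or `candy` |
| version | int | task version 1-4 (3-4 record `t_move`) |
| setting | chr | `in_person` or `online` |
| gender | chr | `male` / `female` / `other` / `unknown` |
| age | num | years, may be NA |
| bmi_group | chr | `<25` / `>=25` / `unknown` |
| smoker | chr | `yes` / `no` / `unknown` |

### trials.csv — one row per offer
| column | type | meaning |
|---|---|---|
| participant_id | chr | key |
| trial_index | int | 0-based, contiguous, in visit order |
| zone_id | int | 0-3 |
| category | chr | reward-category label |
| offered_delay | num | offered delay, s |
| decision | chr | `stay` / `skip` / `quit` |
| t_offer | int | offer presentation = offer-zone entry, ms |
| t_move | int | first movement (versions 3-4 only; NA otherwise) |
| t_exit | int | offer-zone exit, ms |
| t_delay_start | int | delay countdown start (stay/quit trials), ms |
| t_quit_or_complete | int | quit or delay completion, ms |
| waited_s | num | time waited in the delay, s (`= offered_delay` for stays, `< offered_delay` for quits) |
| entry_position | num | signed fraction of hallway width in [-0.5, +0.5]; negative = toward the participant's left and the reward side |

Invariants: `t_offer <= t_move <= t_exit` where present; quits have
`t_delay_start` and `waited_s < offered_delay`; stays completed the full
delay.

### trajectories.csv — position samples within the offer zone
| column | type | meaning |
|---|---|---|
| participant_id | chr | key |
| trial_index | int | trial |
| t | int | ms; strictly increasing within a trial; within `[t_offer, t_exit]` |
| x, y | num | planar position, track units |
| heading | num | facing direction, degrees in [0, 360) |

Samples after the first offer-zone exit (re-entries) are dropped at read
time; the sampling rate is not fixed and all metrics are sample-wise.

### magazine.csv — beam breaks (candy variant)
| column | type | meaning |
|---|---|---|
| participant_id | chr | key |
| zone_id | int | magazine zone |
| t_start | int | break onset, ms |
| duration_ms | int | break duration (> 0) |

Retrieval scoring keeps breaks of 50 ms-10 s (inclusive) starting within the
first 20 min.

## jsonl

One JSON object per line with fields `participant_id`, `task_variant`,
`version`, `setting`, `covariates`, and column-oriented `trials`,
`trajectories`, `magazine` matching the tables above.

## Analysis outputs

All numeric output tables are TSV with one header comment line
(`# rowforage <version> config_hash=<hash>`) recording provenance.
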