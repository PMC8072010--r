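test_that("same seed reproduces the identical session", {
  a <- agent_config()
  s1 <- generate_session(a, task_config(), seed = 11, task_variant = "candy")
  s2 <- generate_session(a, task_config(), seed = 11, task_variant = "candy")
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$magazine, s2$magazine)
  s3 <- generate_session(a, task_config(), seed = 12, task_variant = "candy")
  expect_false(identical(s1$trials, s3$trials))
})

test_that("a zero-temperature agent is a perfect step function of delay", {
  s <- generate_session(step_agent(10), task_config(), seed = 3,
                        include_trajectories = FALSE)
  tr <- s$trials
  expect_true(all(tr$decision[tr$offered_delay < 10] == "stay"))
  expect_true(all(tr$decision[tr$offered_delay >= 10] == "skip"))
  # heterogeneous thresholds apply per category
  s2 <- generate_session(step_agent(c(5, 10, 15, 20)), task_config(), seed = 4,
                         include_trajectories = FALSE)
  th <- c(kittens = 5, accidents = 10, dancing = 15, landscapes = 20)
  expect_true(all((s2$trials$offered_delay < th[s2$trials$category]) ==
                    (s2$trials$decision == "stay")))
})

test_that("full-stay and full-skip styles satisfy the 75% classification rule", {
  a <- agent_config(response_style = "full_stay", quit_hazard_base = 0)
  s <- generate_session(a, task_config(n_circuits = 10), seed = 6,
                        include_trajectories = FALSE)
  expect_gte(mean(s$trials$decision == "stay"), 0.75)
  b <- agent_config(response_style = "full_skip")
  s2 <- generate_session(b, task_config(n_circuits = 10), seed = 6,
                         include_trajectories = FALSE)
  expect_lte(mean(s2$trials$decision == "stay"), 0.25)
})

test_that("deliberation boosts rotation and latency near threshold", {
  # >= 1000 trials from agents with every offer value represented
  ss <- lapply(1:10, function(i)
    generate_session(agent_config(thresholds = 16, deliberation_gain = 2,
                                  quit_hazard_base = 0),
                     task_config(), seed = 100 + i))
  m <- dplyr::bind_rows(lapply(ss, function(s)
    suppressWarnings(offer_zone_metrics(s))))
  gt <- dplyr::bind_rows(lapply(ss, attr, "ground_truth"))
  expect_gte(nrow(m), 1000)
  v <- abs(gt$value_true)
  expect_gt(mean(m$rotation_deg[v <= 1], na.rm = TRUE),
            mean(m$rotation_deg[v >= 10], na.rm = TRUE))
  expect_gt(mean(m$latency_ms[v <= 1], na.rm = TRUE),
            mean(m$latency_ms[v >= 10], na.rm = TRUE))
})

test_that("trajectories reproduce the planned kinematics", {
  s <- generate_session(agent_config(deliberation_gain = 2, thresholds = 16),
                        task_config(n_circuits = 10), seed = 21)
  gt <- attr(s, "ground_truth")
  m <- suppressWarnings(offer_zone_metrics(s))
  # planned pause (reaction + inserted stops) recovered within sampling
  # resolution: each still segment can lose up to ~2 sample intervals
  tol <- 1000 / agent_config()$sample_hz * 2 * (gt$n_vte + 2)
  expect_true(all(abs(m$pause_ms - gt$planned_pause_ms) <= tol))
  # inserted reorientation episodes produce at least k - 1 reversals
  many <- gt$n_vte >= 2
  expect_true(mean(m$n_reversals[many] >= gt$n_vte[many] - 1) > 0.9)
  # planned rotation (bearing + episode excursions) matches measured
  expect_equal(m$rotation_deg, gt$planned_rotation_deg, tolerance = 0.05)
})

test_that("with zero sunk-cost strength the quit process is memoryless", {
  # 10,000 started delays at a fixed 20 s offer; geometric survival expected
  a <- agent_config(response_style = "full_stay", quit_hazard_base = 0.05,
                    sunk_cost_strength = 0, deliberation_gain = 0)
  tk <- task_config(delay_set = 20, draws_without_replacement = FALSE,
                    n_circuits = 2500)
  s <- generate_session(a, tk, seed = 31, include_trajectories = FALSE)
  expect_equal(nrow(s$trials), 10000)
  h <- 0.05
  quit_step <- floor(s$trials$waited_s[s$trials$decision == "quit"])
  obs <- c(tabulate(quit_step + 1L, nbins = 20),
           sum(s$trials$decision == "stay"))
  probs <- c(h * (1 - h)^(0:19), (1 - h)^20)
  gof <- stats::chisq.test(obs, p = probs)
  expect_gt(gof$p.value, 0.01)
})

test_that("quits carry both the 0-coding and the waited time", {
  a <- agent_config(response_style = "full_stay", quit_hazard_base = 0.2,
                    sunk_cost_strength = 0)
  s <- generate_session(a, task_config(), seed = 8, include_trajectories = FALSE)
  q <- s$trials[s$trials$decision == "quit", ]
  expect_gt(nrow(q), 0)
  expect_true(all(q$waited_s < q$offered_delay))
  expect_true(all(!is.na(q$t_delay_start)))
  expect_true(all(choice_points(s)$choice[s$trials$decision == "quit"] == 0))
})

test_that("cohorts are reproducible and prefix-stable in n", {
  c1 <- generate_cohort(3, seed = 9, task = task_config(n_circuits = 2),
                        include_trajectories = FALSE)
  c2 <- generate_cohort(5, seed = 9, task = task_config(n_circuits = 2),
                        include_trajectories = FALSE)
  for (i in 1:3) expect_identical(c1[[i]]$trials, c2[[i]]$trials)
  expect_error(generate_cohort(0), class = "rowforage_config_error")
  expect_warning(generate_cohort(2, prior = list(choice_temperature = 1),
                                 task = task_config(n_circuits = 1),
                                 include_trajectories = FALSE),
                 "zero variance")
})

test_that("cohort covariate effects plant recoverable subgroup differences", {
  ss <- suppressWarnings(generate_cohort(
    30, seed = 13,
    task = task_config(delay_set = c(11, 21), draws_without_replacement = FALSE,
                       n_circuits = 20),
    prior = list(thresholds = 16, choice_temperature = 2, entry_bias_sd = 0.15,
                 deliberation_gain = 0, quit_hazard_base = 0),
    covariate_effects = list(
      bias_choice_coef = function(v, cov) if (cov$gender == "female") 0 else 4),
    include_trajectories = FALSE))
  agents <- attr(ss, "agents")
  vals <- cohort_values(ss)
  dat <- dplyr::left_join(cohort_trials(ss),
                          vals[, c("participant_id", "trial_index", "value_type")],
                          by = c("participant_id", "trial_index"))
  dat$entry_bias <- dat$entry_position
  fit_g <- function(ids) suppressWarnings(fit_entry_bias_model(
    dat[dat$participant_id %in% ids, ]))
  males <- agents$participant_id[agents$gender == "male"]
  females <- agents$participant_id[agents$gender == "female"]
  bm <- fit_g(males)$coefficients
  bf <- fit_g(females)$coefficients
  est <- function(cf) cf$estimate[cf$term == "entry_bias"]
  expect_lt(est(bm), est(bf))  # males carry the planted bias sensitivity
  expect_lt(est(bm), 0)
})

test_that("config validation rejects impossible settings", {
  expect_error(agent_config(choice_temperature = -1),
               class = "rowforage_config_error")
  expect_error(agent_config(response_style = "sideways"),
               class = "rowforage_config_error")
  expect_error(task_config(delay_set = numeric(0)),
               class = "rowforage_config_error")
  expect_error(task_config(crossing_time = 0),
               class = "rowforage_config_error")
  expect_error(task_config(n_circuits = 40, delay_set = 3:29),
               class = "rowforage_config_error")
})

test_that("simulated survey responders behave like hyperbolic discounters", {
  items <- load_item_bank("mcq21")
  expect_true(all(generate_survey_responses(Inf, items) == 0))
  expect_true(all(generate_survey_responses(0, items) == 1))
  r1 <- generate_survey_responses(0.01, items, seed = 2)
  expect_identical(r1, generate_survey_responses(0.01, items, seed = 2))
  # responses split exactly at the implied-k ladder
  expect_identical(r1, as.integer(items$implied_k > 0.01))
})
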