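test_that("without quits the completion curve is flat at 1", {
  ss <- suppressWarnings(
    generate_cohort(5, seed = 51, task = task_config(n_circuits = 10),
                    prior = list(response_style = "full_stay",
                                 quit_hazard_base = 0),
                    include_trajectories = FALSE))
  cc <- suppressWarnings(completion_curves(cohort_trials(ss), bootstrap = 50,
                                           seed = 1))
  expect_true(all(cc$curves$p_complete == 1))
  expect_true(all(cc$slopes$slope == 0))
})

test_that("completion-curve counts are conserved", {
  ss <- suppressWarnings(
    generate_cohort(6, seed = 52,
                    prior = list(response_style = "full_stay",
                                 quit_hazard_base = 0.1,
                                 sunk_cost_strength = 1),
                    include_trajectories = FALSE))
  trials <- cohort_trials(ss)
  cc <- suppressWarnings(completion_curves(trials, investments = c(0, 5),
                                           bootstrap = 0))
  started <- trials[trials$decision %in% c("stay", "quit"), ]
  for (T in c(0, 5)) {
    qual <- started[started$waited_s >= T & round(started$offered_delay) > T, ]
    cv <- cc$curves[cc$curves$invested == T, ]
    expect_equal(sum(cv$n), nrow(qual))
    expect_equal(sum(cv$n_complete), sum(qual$decision == "stay"))
    # every qualifying trial either completes or quits after T
    expect_equal(sum(cv$n) - sum(cv$n_complete), sum(qual$decision == "quit"))
  }
})

test_that("the entry-bias model needs multiple participants and both value types", {
  d <- data.frame(participant_id = "one", choice = rbinom(40, 1, 0.5),
                  value_type = rep(c("good", "poor"), 20),
                  entry_bias = runif(40, -0.5, 0.5))
  expect_error(fit_entry_bias_model(d), class = "rowforage_data_error")
  d2 <- data.frame(participant_id = rep(c("a", "b"), each = 20),
                   choice = rbinom(40, 1, 0.5), value_type = "good",
                   entry_bias = runif(40, -0.5, 0.5))
  expect_error(fit_entry_bias_model(d2), class = "rowforage_data_error")
})

test_that("separated participants are clamped with a warning", {
  set.seed(61)
  d <- data.frame(participant_id = rep(c("a", "b", "c"), each = 40),
                  value_type = rep(c("good", "poor"), 60),
                  entry_bias = runif(120, -0.4, 0.4))
  d$choice <- rbinom(120, 1, plogis(ifelse(d$value_type == "good", 1, -1)))
  d$choice[d$participant_id == "c"] <- 1L
  expect_warning(m <- fit_entry_bias_model(d), "clamped")
  expect_true(all(is.finite(m$coefficients$estimate)))
  expect_true(is.finite(m$participant_intercepts["c"]))
})

test_that("bias-effect predictions match the closed-form logistic difference", {
  # hand-built model with known coefficients: an independent analytic oracle
  model <- structure(list(
    coefficients = tibble::tibble(
      term = c("value_dev", "entry_bias", "value_dev:entry_bias"),
      estimate = c(-3, -1.6, 0.4), se = NA, ci_lo = NA, ci_hi = NA),
    participant_intercepts = c(a = -0.2, b = 0.5, c = 0.1),
    include_gender = FALSE, n_trials = 0, fit = NULL),
    class = "entry_bias_model")
  out <- bias_effect_summary(model, bias_points = c(-25, 25))
  alphas <- c(-0.2, 0.5, 0.1)
  p_poor <- function(f) mean(plogis(alphas - 3 * 0.5 - 1.6 * f + 0.4 * 0.5 * f))
  p_good <- function(f) mean(plogis(alphas + 3 * 0.5 - 1.6 * f - 0.4 * 0.5 * f))
  expect_equal(out$poor_accept_change_pp[out$bias_pct == -25],
               100 * (p_poor(-0.25) - p_poor(0)), tolerance = 1e-6)
  expect_equal(out$good_skip_change_pp[out$bias_pct == 25],
               100 * ((1 - p_good(0.25)) - (1 - p_good(0))), tolerance = 1e-6)
  # a zero bias coefficient predicts exactly no change
  model$coefficients$estimate[2:3] <- 0
  out0 <- bias_effect_summary(model, bias_points = c(-25, 25))
  expect_equal(out0$poor_accept_change_pp, c(0, 0))
  expect_equal(out0$good_skip_change_pp, c(0, 0))
  expect_error(bias_effect_summary(model, bias_points = 60),
               class = "rowforage_config_error")
})

test_that("a planted entry-bias effect is recovered with the correct sign", {
  ss <- suppressWarnings(generate_cohort(
    30, seed = 63,
    task = task_config(delay_set = c(11, 21), draws_without_replacement = FALSE,
                       n_circuits = 20),
    prior = list(thresholds = 16, choice_temperature = 2, bias_choice_coef = 3,
                 entry_bias_sd = 0.15, deliberation_gain = 0,
                 quit_hazard_base = 0),
    include_trajectories = FALSE))
  vals <- cohort_values(ss)
  dat <- dplyr::left_join(cohort_trials(ss),
                          vals[, c("participant_id", "trial_index", "value_type")],
                          by = c("participant_id", "trial_index"))
  dat$entry_bias <- dat$entry_position
  m <- suppressWarnings(fit_entry_bias_model(dat))
  eb <- m$coefficients[m$coefficients$term == "entry_bias", ]
  expect_lt(eb$estimate, 0)  # rightward entries reduce acceptance
  expect_lt(eb$ci_hi, 0)
  # the model's predicted bias effects go the observed directions
  eff <- bias_effect_summary(m, bias_points = c(-25, 25))
  expect_gt(eff$poor_accept_change_pp[eff$bias_pct == -25], 0)
  expect_gt(eff$good_skip_change_pp[eff$bias_pct == 25], 0)
})
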