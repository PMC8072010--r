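test_that("padding adds one stay below and one skip above the offered range", {
  pts <- data.frame(delay = 3:29, choice = rep(1, 27))
  padded <- pad_choices(pts)
  expect_equal(nrow(padded), 29)
  pads <- padded[padded$padded, ]
  expect_equal(sort(pads$delay), c(2, 30))
  expect_equal(pads$choice[order(pads$delay)], c(1, 0))
  one <- pad_choices(data.frame(delay = 10, choice = 1))
  expect_equal(sort(one$delay), c(9, 10, 11))
  expect_equal(one$choice[order(one$delay)], c(1, 1, 0))
  expect_error(pad_choices(padded), "already padded")
  expect_error(pad_choices(data.frame(delay = numeric(0), choice = numeric(0))),
               "empty")
})

test_that("the Heaviside fit minimizes misclassifications with midpoint candidates", {
  pts <- pad_choices(data.frame(delay = c(3, 5, 10, 15),
                                choice = c(1, 1, 0, 0)))
  f <- fit_heaviside(pts)
  expect_equal(f$threshold, 7.5)
  expect_equal(f$error, 0)
  # all stays: padding forces the step just above the maximum real delay
  all_stay <- pad_choices(data.frame(delay = 3:29, choice = rep(1, 27)))
  f2 <- fit_heaviside(all_stay)
  expect_equal(f2$threshold, 29.5)
  expect_equal(f2$error, 0)
  expect_error(fit_heaviside(data.frame(delay = 1:3, choice = c(1, 0, 0))),
               "padded")
})

test_that("the step fit matches a dense brute-force grid scan on random sets", {
  set.seed(77)
  for (r in 1:500) {
    n <- sample(3:20, 1)
    pts <- pad_choices(data.frame(delay = sample(3:29, n, replace = TRUE),
                                  choice = stats::rbinom(n, 1, runif(1))))
    f <- fit_heaviside(pts)
    o <- oracle_grid_step(pts$delay, pts$choice)
    expect_equal(f$error, o$error)
    # the threshold (mean of minimizing candidates, which may tie across
    # disjoint regions) stays within the oracle's minimizing envelope

    expect_gte(f$threshold, o$minimizers[1] - 0.101)
    expect_lte(f$threshold, o$minimizers[length(o$minimizers)] + 0.101)
  }
})

test_that("leave-one-out thresholds bracket a noiseless step agent", {
  pts <- data.frame(delay = 3:29, choice = as.integer(3:29 < 10))
  loo <- loo_thresholds(pts)
  for (i in seq_len(nrow(loo))) {
    rest <- pts[-i, ]
    lo <- max(rest$delay[rest$choice == 1])
    hi <- min(rest$delay[rest$choice == 0])
    expect_gt(loo$loo_threshold[i], lo)
    expect_lt(loo$loo_threshold[i], hi)
  }
  expect_lt(abs(mean(loo$loo_threshold) - 9.5), 0.6)
})

test_that("two real points are the smallest legal leave-one-out input", {
  loo <- loo_thresholds(data.frame(delay = c(5, 20), choice = c(1, 0),
                                   trial_index = c(0, 1)))
  # each subfit pads a single held-in point: (20,0) -> 19.5, (5,1) -> 5.5
  expect_equal(loo$loo_threshold, c(19.5, 5.5))
  expect_equal(loo$loo_error, c(0, 0))
  expect_error(loo_thresholds(data.frame(delay = 5, choice = 1)),
               "at least 2")
})

test_that("duplicating every choice point leaves the overall threshold unchanged", {
  set.seed(5)
  pts <- data.frame(delay = sample(3:29, 15), choice = rbinom(15, 1, 0.5))
  t1 <- mean(loo_thresholds(pts)$loo_threshold)
  dup <- rbind(pts, pts)
  dup$trial_index <- seq_len(nrow(dup)) - 1L
  t2 <- mean(loo_thresholds(dup)$loo_threshold)
  expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("response patterns are classified by the forward/inverse error rule", {
  expect_equal(classify_pattern(0.5, 3, 0.4), "normal")
  expect_equal(classify_pattern(3, 0.5, 0.6), "long_delay_pref")
  expect_equal(classify_pattern(1, 1, 1.0), "full_stay")
  expect_equal(classify_pattern(1, 1, 0.1), "full_skip")
  expect_equal(classify_pattern(1, 1, 0.5), "unclassified")
  expect_equal(classify_pattern(1, 1, 0.75), "full_stay")
  expect_equal(classify_pattern(1, 1, 0.25), "full_skip")
})

test_that("a reversed agent is classified as preferring long delays", {
  a <- agent_config(thresholds = 16, choice_temperature = 0,
                    response_style = "reversed", bias_choice_coef = 0,
                    quit_hazard_base = 0, deliberation_gain = 0)
  s <- generate_session(a, task_config(), seed = 41, include_trajectories = FALSE)
  f <- fit_thresholds(s)
  expect_true(all(f$summary$pattern == "long_delay_pref"))
  expect_true(all(f$summary$inverse_error < f$summary$forward_error))
  # values are unavailable outside the normal pattern
  expect_true(all(is.na(f$trials$value)))
})

test_that("full-stay sessions tie the fits and classify by acceptance", {
  a <- agent_config(response_style = "full_stay", quit_hazard_base = 0)
  s <- generate_session(a, task_config(), seed = 42, include_trajectories = FALSE)
  f <- fit_thresholds(s)
  expect_true(all(f$summary$forward_error == f$summary$inverse_error))
  expect_true(all(f$summary$pattern == "full_stay"))
})

test_that("offer value follows the threshold-minus-offer convention", {
  v <- offer_value(c(6, 10, 15), 10)
  expect_equal(v$value, c(4, 0, -5))
  expect_equal(v$value_type, c("good", "boundary", "poor"))
  expect_equal(v$abs_value, c(4, 0, 5))
  unavailable <- offer_value(6, 10, pattern = "full_stay")
  expect_true(is.na(unavailable$value))
})

test_that("categories with fewer than two real trials are unclassified", {
  tr <- data.frame(category = c("a", "a", "a", "b"),
                   trial_index = 0:3, delay = c(4, 12, 20, 10),
                   choice = c(1, 1, 0, 1))
  names(tr)[3] <- "delay"
  f <- fit_thresholds(tr)
  expect_equal(f$summary$pattern[f$summary$category == "b"], "unclassified")
  expect_true(is.na(f$summary$overall_threshold[f$summary$category == "b"]))
  expect_equal(f$summary$pattern[f$summary$category == "a"], "normal")
})
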