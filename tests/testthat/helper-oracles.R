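# Independent brute-force oracles and small builders shared across tests.
# The oracles deliberately use naive loops / dense scans so they share no
# code path with the implementations they check.

oracle_distance <- function(x, y) {
  total <- 0
  for (i in seq_len(length(x) - 1)) {
    total <- total + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  total
}

oracle_wrap <- function(d) {
  while (d <= -180) d <- d + 360
  while (d > 180) d <- d - 360
  d
}

oracle_rotation <- function(heading) {
  total <- 0
  for (i in seq_len(length(heading) - 1)) {
    total <- total + abs(oracle_wrap(heading[i + 1] - heading[i]))
  }
  total
}

oracle_reversals <- function(heading, jitter = 1) {
  incs <- c()
  for (i in seq_len(length(heading) - 1)) {
    d <- oracle_wrap(heading[i + 1] - heading[i])
    if (abs(d) >= jitter) incs <- c(incs, d)
  }
  if (length(incs) < 2) return(0L)
  sum(sign(incs[-1]) != sign(incs[-length(incs)]))
}

# Dense grid scan for the step fit: min error and the grid minimizers.
oracle_grid_step <- function(delay, choice, step = 0.1) {
  grid <- seq(min(delay) - 1, max(delay) + 1, by = step)
  err <- vapply(grid, function(th) sum((delay < th) != (choice == 1)),
                numeric(1))
  list(error = min(err), minimizers = grid[err == min(err)])
}

# Dense log-grid scan for survey scoring: maximal consistency and the k
# interval attaining it.
oracle_survey_k <- function(responses, implied_k, n_grid = 4000) {
  grid <- exp(seq(log(min(implied_k)) - 2, log(max(implied_k)) + 2,
                  length.out = n_grid))
  cons <- vapply(grid, function(k) mean((implied_k > k) == (responses == 1)),
                 numeric(1))
  list(consistency = max(cons), k_range = range(grid[cons == max(cons)]))
}

# A tiny hand-assembled session with a fixed trajectory per trial.
make_manual_session <- function(n_trials = 2, version = 2) {
  trials <- data.frame(
    trial_index = seq_len(n_trials) - 1L, zone_id = (seq_len(n_trials) - 1L) %% 4L,
    category = rep(c("kittens", "accidents", "dancing", "landscapes"),
                   length.out = n_trials),
    offered_delay = rep(c(5, 20), length.out = n_trials),
    decision = rep(c("stay", "skip"), length.out = n_trials),
    t_offer = (seq_len(n_trials) - 1L) * 10000L,
    t_move = (seq_len(n_trials) - 1L) * 10000L + 500L,
    t_exit = (seq_len(n_trials) - 1L) * 10000L + 2000L,
    t_delay_start = ifelse(rep(c(TRUE, FALSE), length.out = n_trials),
                           (seq_len(n_trials) - 1L) * 10000L + 3000L, NA),
    t_quit_or_complete = ifelse(rep(c(TRUE, FALSE), length.out = n_trials),
                                (seq_len(n_trials) - 1L) * 10000L + 8000L, NA),
    waited_s = ifelse(rep(c(TRUE, FALSE), length.out = n_trials), 5, NA),
    entry_position = 0.1)
  traj <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    t0 <- trials$t_offer[i]
    data.frame(trial_index = i - 1L, t = t0 + seq(0, 1500, by = 500),
               x = c(0, 0.1, 0.2, 0.3), y = c(0, 0.3, 0.6, 0.9),
               heading = c(10, 15, 20, 25))
  }))
  new_session("manual", trials, trajectories = traj, version = version)
}

# Standard noiseless step agent used by several tests.
step_agent <- function(thresholds, ...) {
  agent_config(thresholds = thresholds, choice_temperature = 0,
               bias_choice_coef = 0, quit_hazard_base = 0,
               deliberation_gain = 0, ...)
}

cohort_trials <- function(sessions) {
  dplyr::bind_rows(lapply(sessions, function(s)
    dplyr::mutate(s$trials, participant_id = s$participant_id)))
}

cohort_values <- function(sessions) {
  dplyr::bind_rows(lapply(sessions, function(s) fit_thresholds(s)$trials))
}
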