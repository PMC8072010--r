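#' Agent configuration for the synthetic forager
#'
#' Defines a ground-truth decision maker for [generate_session()]. Choices
#' follow a logistic rule on offer value, `P(stay) = logistic((theta_c -
#' delay) / tau - beta_bias * entry_position)`, where `theta_c` is the
#' per-category delay threshold (s) and `tau` the choice temperature (s);
#' `tau = 0` gives a deterministic Heaviside agent (stay iff delay < theta,
#' the entry-bias term vanishing in the limit). The `reversed` response style
#' flips the sign of the value term (a long-delay-preference agent);
#' `full_stay` / `full_skip` ignore the delay entirely.
#'
#' Deliberation: near-threshold offers receive `N ~ Poisson(g(|value|))`
#' reorientation episodes with `g(v) = deliberation_gain *
#' exp(-v / deliberation_width)`, each a heading excursion plus an optional
#' pause, lengthening latency, rotation, reversals and pausing exactly where
#' the value-tuning analyses predict. Value here uses the agent's true
#' threshold, not an estimate.
#'
#' Quitting: once the delay starts, a per-second hazard
#' `h(t) = quit_hazard_base / (1 + sunk_cost_strength * t)` is applied in 1-s
#' steps of time invested `t`; `sunk_cost_strength = 0` gives a memoryless
#' (geometric-survival) quitter, positive values a sunk-cost-sensitive one.
#' The defaults give the rare quits (<1% of started delays) seen in humans.
#'
#' @param thresholds Per-category delay thresholds theta_c in seconds
#'   (length 1 or 4, recycled).
#' @param choice_temperature Logistic temperature tau in seconds; 0 =
#'   deterministic.
#' @param response_style One of `"normal"`, `"reversed"`, `"full_stay"`,
#'   `"full_skip"` per category (length 1 or 4, recycled).
#' @param entry_bias_sd SD of the entry position (fraction of hallway width;
#'   draws are truncated to \[-0.5, 0.5\]).
#' @param bias_choice_coef beta_bias: effect of entry position (fraction
#'   units) on the stay log-odds; positive values make rightward (exit-side)
#'   entries less likely to stay.
#' @param deliberation_gain,deliberation_width Gain (expected episodes at
#'   value 0) and width (s) of the near-threshold VTE boost.
#' @param base_latency Median pre-movement reaction time, ms (lognormal
#'   jitter with sdlog 0.25).
#' @param quit_hazard_base Per-second quit hazard at zero time invested.
#' @param sunk_cost_strength Hazard decay with invested time (>= 0).
#' @param episode_rotation_range Heading excursion per VTE episode, degrees.
#' @param episode_pause_range Pause duration per episode, ms.
#' @param episode_pause_prob Probability an episode includes a pause.
#' @param rotation_speed Head-turn speed during excursions, degrees/s.
#' @param sample_hz Trajectory sampling rate (the task log rate is not fixed
#'   by the protocol; metrics are rate-agnostic).
#' @return An `agent_config` object.
#' @export
agent_config <- function(thresholds = c(10, 14, 19, 24),
                         choice_temperature = 1,
                         response_style = "normal",
                         entry_bias_sd = 0.1,
                         bias_choice_coef = 2,
                         deliberation_gain = 1,
                         deliberation_width = 3,
                         base_latency = 700,
                         quit_hazard_base = 0.002,
                         sunk_cost_strength = 1,
                         episode_rotation_range = c(60, 120),
                         episode_pause_range = c(200, 800),
                         episode_pause_prob = 0.5,
                         rotation_speed = 150,
                         sample_hz = 20) {
  styles <- c("normal", "reversed", "full_stay", "full_skip")
  response_style <- rep(as.character(response_style), length.out = 4)
  if (!all(response_style %in% styles))
    rlang::abort(paste0("response_style must be one of: ",
                        paste(styles, collapse = ", ")),
                 class = "rowforage_config_error")
  thresholds <- rep(as.numeric(thresholds), length.out = 4)
  for (nm in c("choice_temperature", "entry_bias_sd", "deliberation_gain",
               "deliberation_width", "base_latency", "quit_hazard_base",
               "sunk_cost_strength", "rotation_speed", "sample_hz")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      rlang::abort(paste0("`", nm, "` must be a single non-negative number"),
                   class = "rowforage_config_error")
  }
  if (quit_hazard_base > 1)
    rlang::abort("`quit_hazard_base` is a per-second probability (<= 1)",
                 class = "rowforage_config_error")
  structure(list(thresholds = thresholds,
                 choice_temperature = choice_temperature,
                 response_style = response_style,
                 entry_bias_sd = entry_bias_sd,
                 bias_choice_coef = bias_choice_coef,
                 deliberation_gain = deliberation_gain,
                 deliberation_width = deliberation_width,
                 base_latency = base_latency,
                 quit_hazard_base = quit_hazard_base,
                 sunk_cost_strength = sunk_cost_strength,
                 episode_rotation_range = episode_rotation_range,
                 episode_pause_range = episode_pause_range,
                 episode_pause_prob = episode_pause_prob,
                 rotation_speed = rotation_speed,
                 sample_hz = sample_hz),
            class = "agent_config")
}

#' Task configuration for the synthetic forager
#'
#' @param delay_set Delays (s) offered per category; the task draws them
#'   without replacement by default, so each category sees each delay once
#'   per sweep (3-29 s by default).
#' @param draws_without_replacement Draw delays without replacement within a
#'   category (one full sweep) or with replacement.
#' @param n_circuits Number of track circuits (one offer per zone per
#'   circuit). Defaults to `length(delay_set)` so that every delay is offered
#'   once per category.
#' @param max_offers Optional cap on the total number of offers.
#' @param version Task version 1-4; versions 3-4 record `t_move` (gated
#'   offer-zone entry), enabling reaction time.
#' @param hallway_width Hallway width in track units.
#' @param crossing_time Time to cross the full hallway width at travel speed,
#'   seconds (about 1.25 s in the task).
#' @return A `task_config` object.
#' @export
task_config <- function(delay_set = 3:29, draws_without_replacement = TRUE,
                        n_circuits = NULL, max_offers = NULL, version = 4L,
                        hallway_width = 1, crossing_time = 1.25) {
  if (length(delay_set) < 1)
    rlang::abort("`delay_set` must be non-empty", class = "rowforage_config_error")
  if (!is.numeric(crossing_time) || crossing_time <= 0)
    rlang::abort("`crossing_time` must be > 0", class = "rowforage_config_error")
  if (!is.numeric(hallway_width) || hallway_width <= 0)
    rlang::abort("`hallway_width` must be > 0", class = "rowforage_config_error")
  version <- as.integer(version)
  if (!version %in% 1:4)
    rlang::abort("`version` must be 1-4", class = "rowforage_config_error")
  if (is.null(n_circuits)) n_circuits <- length(delay_set)
  n_circuits <- as.integer(n_circuits)
  if (n_circuits < 1)
    rlang::abort("`n_circuits` must be >= 1", class = "rowforage_config_error")
  if (draws_without_replacement && n_circuits > length(delay_set))
    rlang::abort("without replacement, `n_circuits` cannot exceed length(delay_set)",
                 class = "rowforage_config_error")
  structure(list(delay_set = as.numeric(delay_set),
                 draws_without_replacement = isTRUE(draws_without_replacement),
                 n_circuits = n_circuits, max_offers = max_offers,
                 version = version, hallway_width = hallway_width,
                 crossing_time = crossing_time),
            class = "task_config")
}

.movie_categories <- c("kittens", "accidents", "dancing", "landscapes")
.candy_categories <- c("mms", "skittles", "reeses", "other")

# Stay/skip choice under the agent's response style. tau = 0 is the
# deterministic limit: the value term dominates any finite bias term, with
# value exactly 0 resolved as skip.
.sim_stay <- function(delay, theta, style, tau, beta, entry, u) {
  lin <- switch(style,
                normal = theta - delay,
                reversed = delay - theta,
                full_stay = return(rep(TRUE, length(delay))),
                full_skip = return(rep(FALSE, length(delay))))
  if (tau == 0) return(lin > 0)
  u < stats::plogis(lin / tau - beta * entry)
}

# Quit step (whole seconds invested before quitting) or NA for completion.
.sim_quit_step <- function(delay, h0, strength) {
  if (h0 <= 0) return(NA_integer_)
  steps <- 0:(ceiling(delay) - 1)
  hz <- h0 / (1 + strength * steps)
  hit <- which(stats::runif(length(steps)) < hz)
  if (length(hit) == 0) NA_integer_ else steps[hit[1]]
}

# Piecewise-linear kinematic plan for one offer-zone pass: stand (reaction),
# orient toward the chosen exit, travel at constant speed with VTE episodes
# (paused heading excursion out and back, optional full stop) inserted at
# pre-drawn fractions of the path. Returns segment table plus ground truth.
.plan_pass <- function(entry_frac, stay, reaction_s, episodes, speed, width,
                       rotation_speed) {
  x0 <- entry_frac * width
  exit_x <- if (stay) -width / 2 else width / 2
  exit_y <- width
  dx <- exit_x - x0
  bearing <- atan2(dx, exit_y) * 180 / pi
  dist <- sqrt(dx^2 + exit_y^2)
  travel_s <- dist / speed
  n_ep <- length(episodes$amp)

  seg <- function(dur, xa, xb, ya, yb, ha, hb) c(dur, xa, xb, ya, yb, ha, hb)
  segs <- list(seg(reaction_s, x0, x0, 0, 0, 0, 0),
               seg(0.25, x0, x0, 0, 0, 0, bearing))
  prev <- 0
  pos <- function(f) c(x0 + f * dx, f * exit_y)
  if (n_ep > 0) {
    for (j in seq_len(n_ep)) {
      f <- episodes$frac[j]
      a <- pos(prev); b <- pos(f)
      segs[[length(segs) + 1]] <- seg((f - prev) * travel_s, a[1], b[1], a[2], b[2],
                                      bearing, bearing)
      amp <- episodes$amp[j] * episodes$dir[j]
      rot_s <- abs(amp) / rotation_speed
      segs[[length(segs) + 1]] <- seg(rot_s, b[1], b[1], b[2], b[2], bearing,
                                      bearing + amp)
      segs[[length(segs) + 1]] <- seg(rot_s, b[1], b[1], b[2], b[2],
                                      bearing + amp, bearing)
      if (episodes$pause_s[j] > 0)
        segs[[length(segs) + 1]] <- seg(episodes$pause_s[j], b[1], b[1], b[2],
                                        b[2], bearing, bearing)
      prev <- f
    }
  }
  a <- pos(prev)
  segs[[length(segs) + 1]] <- seg((1 - prev) * travel_s, a[1], exit_x, a[2],
                                  exit_y, bearing, bearing)
  m <- do.call(rbind, segs)
  colnames(m) <- c("dur", "x0", "x1", "y0", "y1", "h0", "h1")
  list(segments = m,
       total_s = sum(m[, "dur"]),
       bearing = bearing,
       planned_rotation = abs(bearing) + 2 * sum(episodes$amp),
       planned_pause_ms = 1000 * (reaction_s + sum(episodes$pause_s)),
       distance = dist)
}

# Sample a planned pass at sample_hz; headings are built unwrapped then
# mapped to [0, 360).
.sample_pass <- function(plan, hz) {
  m <- plan$segments
  m <- m[m[, "dur"] > 0, , drop = FALSE]
  ends <- cumsum(m[, "dur"])
  starts <- c(0, utils::head(ends, -1))
  total <- ends[length(ends)]
  tt <- seq(0, total, by = 1 / hz)
  idx <- pmin(findInterval(tt, starts), nrow(m))
  f <- (tt - starts[idx]) / m[idx, "dur"]
  f[!is.finite(f)] <- 0
  h <- (m[idx, "h0"] + f * (m[idx, "h1"] - m[idx, "h0"])) %% 360
  h[h >= 360] <- 0  # guard the float seam (tiny negatives wrap to 360.0)
  list(t_rel = tt,
       x = m[idx, "x0"] + f * (m[idx, "x1"] - m[idx, "x0"]),
       y = m[idx, "y0"] + f * (m[idx, "y1"] - m[idx, "y0"]),
       heading = h)
}

#' Simulate one foraging session with known ground truth
#'
#' Generates a [new_session()] whose choices, trajectories, quits and (for the
#' candy variant) magazine events follow the generative model described in
#' [agent_config()]. Deterministic given `seed`. The per-trial ground truth
#' (true offer value, inserted VTE episodes, planned pause and rotation) is
#' attached as `attr(session, "ground_truth")` for parameter-recovery tests.
#'
#' @param agent An [agent_config()].
#' @param task A [task_config()].
#' @param seed Integer seed; `NULL` uses (and advances) the ambient RNG
#'   stream.
#' @param participant_id,task_variant,setting,covariates Session metadata.
#' @param include_trajectories Sample position data (default). Turning this
#'   off skips sampling (the kinematic plan and all timestamps are identical)
#'   for large choice-only simulations.
#' @return A `row_session`.
#' @export
generate_session <- function(agent = agent_config(), task = task_config(),
                             seed = NULL, participant_id = "S001",
                             task_variant = c("movie", "candy"),
                             setting = c("in_person", "online"),
                             covariates = list(),
                             include_trajectories = TRUE) {
  stopifnot(inherits(agent, "agent_config"), inherits(task, "task_config"))
  task_variant <- match.arg(task_variant)
  setting <- match.arg(setting)
  .with_seed(seed, {
    categories <- if (task_variant == "movie") .movie_categories else .candy_categories
    nc <- task$n_circuits
    # sample() treats a length-1 x as 1:x; index-based draws avoid that
    draw_delays <- function() {
      idx <- sample.int(length(task$delay_set), nc,
                        replace = !task$draws_without_replacement)
      task$delay_set[idx]
    }
    delays_by_cat <- vapply(1:4, function(z) draw_delays(), numeric(nc))
    if (nc == 1) delays_by_cat <- matrix(delays_by_cat, nrow = 1)

    n <- nc * 4L
    if (!is.null(task$max_offers)) n <- min(n, as.integer(task$max_offers))
    zone <- rep(0:3, times = nc)[seq_len(n)]
    circuit <- rep(seq_len(nc), each = 4)[seq_len(n)]
    delay <- delays_by_cat[cbind(circuit, zone + 1)]
    theta <- agent$thresholds[zone + 1]
    style <- agent$response_style[zone + 1]

    entry <- pmin(pmax(stats::rnorm(n, 0, agent$entry_bias_sd), -0.5), 0.5)
    u <- stats::runif(n)
    stay <- logical(n)
    for (st in unique(style)) {
      i <- style == st
      stay[i] <- .sim_stay(delay[i], theta[i], st, agent$choice_temperature,
                           agent$bias_choice_coef, entry[i], u[i])
    }

    waited <- ifelse(stay, delay, NA_real_)
    decision <- ifelse(stay, "stay", "skip")
    for (i in which(stay)) {
      q <- .sim_quit_step(delay[i], agent$quit_hazard_base,
                          agent$sunk_cost_strength)
      if (!is.na(q)) {
        decision[i] <- "quit"
        waited[i] <- q + 0.5  # quit mid-step; keeps waited < delay
      }
    }

    reaction_ms <- round(agent$base_latency * exp(stats::rnorm(n, 0, 0.25)))
    value_true <- theta - delay
    g <- agent$deliberation_gain * exp(-abs(value_true) / agent$deliberation_width)
    n_vte <- stats::rpois(n, g)
    episodes <- lapply(seq_len(n), function(i) {
      k <- n_vte[i]
      if (k == 0)
        return(list(frac = numeric(0), amp = numeric(0), dir = numeric(0),
                    pause_s = numeric(0)))
      list(frac = sort(stats::runif(k, 0.15, 0.85)),
           amp = stats::runif(k, agent$episode_rotation_range[1],
                              agent$episode_rotation_range[2]),
           dir = sample(c(-1, 1), 1) * (-1)^(seq_len(k) - 1),
           pause_s = ifelse(stats::runif(k) < agent$episode_pause_prob,
                            stats::runif(k, agent$episode_pause_range[1],
                                         agent$episode_pause_range[2]) / 1000,
                            0))
    })

    speed <- task$hallway_width / task$crossing_time
    plans <- lapply(seq_len(n), function(i) {
      .plan_pass(entry[i], decision[i] != "skip", reaction_ms[i] / 1000,
                 episodes[[i]], speed, task$hallway_width, agent$rotation_speed)
    })
    pass_ms <- vapply(plans, function(p) round(1000 * p$total_s), numeric(1))

    # Session clock: offer-zone pass, then transit to the next zone; stays
    # additionally walk to the platform, wait out the delay (or quit), and
    # consume the reward when it is earned.
    stayish <- decision != "skip"
    occupancy <- pass_ms + 5000 +
      ifelse(stayish, 1000 + round(1000 * waited) +
               ifelse(decision == "stay", 4000, 0), 0)
    t_offer <- cumsum(c(0, utils::head(occupancy, -1)))
    t_move <- t_offer + reaction_ms
    t_exit <- t_offer + pass_ms
    t_delay_start <- ifelse(stayish, t_exit + 1000, NA_real_)
    t_quit_or_complete <- ifelse(stayish, t_delay_start + round(1000 * waited),
                                 NA_real_)

    trials <- data.frame(trial_index = seq_len(n) - 1L, zone_id = zone,
                         category = categories[zone + 1],
                         offered_delay = delay, decision = decision,
                         t_offer = t_offer,
                         t_move = if (task$version >= 3) t_move else NA,
                         t_exit = t_exit, t_delay_start = t_delay_start,
                         t_quit_or_complete = t_quit_or_complete,
                         waited_s = waited, entry_position = entry,
                         stringsAsFactors = FALSE)

    traj <- NULL
    if (include_trajectories) {
      samp <- lapply(plans, .sample_pass, hz = agent$sample_hz)
      len <- vapply(samp, function(s) length(s$t_rel), integer(1))
      traj <- data.frame(
        trial_index = rep(seq_len(n) - 1L, len),
        t = rep(t_offer, len) +
          round(1000 * unlist(lapply(samp, `[[`, "t_rel"), use.names = FALSE)),
        x = unlist(lapply(samp, `[[`, "x"), use.names = FALSE),
        y = unlist(lapply(samp, `[[`, "y"), use.names = FALSE),
        heading = unlist(lapply(samp, `[[`, "heading"), use.names = FALSE))
    }

    magazine <- NULL
    if (task_variant == "candy") {
      earned <- which(decision == "stay")
      magazine <- data.frame(zone_id = zone[earned],
                             t_start = t_quit_or_complete[earned] + 800,
                             duration_ms = round(stats::runif(length(earned), 400, 2500)))
      # spurious short/long breaks exercise the 50 ms-10 s retrieval filter
      n_spur <- stats::rpois(1, 3)
      if (n_spur > 0) {
        spur <- data.frame(zone_id = sample(0:3, n_spur, replace = TRUE),
                           t_start = round(stats::runif(n_spur, 0,
                                                        max(t_exit) + 6e5)),
                           duration_ms = round(exp(stats::runif(n_spur,
                                                                log(10), log(30000)))))
        magazine <- rbind(magazine, spur)
      }
    }

    session <- new_session(participant_id = participant_id, trials = trials,
                           trajectories = traj, magazine = magazine,
                           task_variant = task_variant, version = task$version,
                           setting = setting, covariates = covariates)
    attr(session, "ground_truth") <- tibble::tibble(
      trial_index = seq_len(n) - 1L, category = categories[zone + 1],
      theta = theta, value_true = value_true, style = style, n_vte = n_vte,
      planned_rotation_deg = vapply(plans, `[[`, numeric(1), "planned_rotation"),
      planned_pause_ms = vapply(plans, `[[`, numeric(1), "planned_pause_ms"),
      planned_latency_ms = pass_ms, entry_position = entry)
    attr(session, "agent") <- agent
    session
  })
}

#' Simulate a cohort with participant-level parameter draws
#'
#' Draws each participant's [agent_config()] fields from `prior`, optionally
#' modifies them as a function of sampled covariates, and generates one
#' session per participant. Child RNG streams are a pure function of
#' `(seed, participant index)`, so enlarging the cohort never perturbs
#' earlier participants.
#'
#' @param n_participants Number of participants (>= 1).
#' @param prior Named list of [agent_config()] fields; each element is either
#'   a fixed value or a zero-argument function drawn once per participant.
#'   The default draws heterogeneous per-category thresholds
#'   `runif(4, 6, 26)`.
#' @param covariate_effects Optional named list of functions
#'   `function(value, covariates)` applied to the drawn field, enabling
#'   planted subgroup differences (e.g. a reduced entry-bias coefficient for
#'   one gender).
#' @param task A [task_config()] shared by the cohort.
#' @param task_variant,setting Passed to [generate_session()].
#' @param seed Master seed.
#' @param include_trajectories Passed to [generate_session()].
#' @return A list of `row_session`s with a tibble of drawn agent parameters
#'   attached as `attr(, "agents")`.
#' @export
generate_cohort <- function(n_participants,
                            prior = list(thresholds = function() stats::runif(4, 6, 26)),
                            covariate_effects = NULL,
                            task = task_config(),
                            task_variant = c("movie", "candy"),
                            setting = c("in_person", "online"),
                            seed = 1L, include_trajectories = TRUE) {
  if (!is.numeric(n_participants) || n_participants < 1)
    rlang::abort("`n_participants` must be >= 1",
                 class = "rowforage_config_error")
  task_variant <- match.arg(task_variant)
  setting <- match.arg(setting)
  n_participants <- as.integer(n_participants)
  if (n_participants > 1 && length(prior) > 0 &&
      !any(vapply(prior, is.function, logical(1))))
    rlang::warn("prior has zero variance across participants; parameter recovery will be degenerate")

  agents <- vector("list", n_participants)
  sessions <- lapply(seq_len(n_participants), function(i) {
    .with_seed(.child_seed(seed, i), {
      cov <- list(gender = sample(c("male", "female"), 1),
                  age = round(stats::runif(1, 18, 65)),
                  bmi_group = sample(c("<25", ">=25"), 1),
                  smoker = sample(c("no", "yes"), 1, prob = c(0.8, 0.2)))
      fields <- lapply(prior, function(p) if (is.function(p)) p() else p)
      if (!is.null(covariate_effects)) {
        defaults <- agent_config()
        for (nm in names(covariate_effects)) {
          base <- if (nm %in% names(fields)) fields[[nm]] else defaults[[nm]]
          fields[[nm]] <- covariate_effects[[nm]](base, cov)
        }
      }
      agent <- do.call(agent_config, fields)
      agents[[i]] <<- tibble::tibble(
        participant_id = sprintf("S%03d", i),
        theta_1 = agent$thresholds[1], theta_2 = agent$thresholds[2],
        theta_3 = agent$thresholds[3], theta_4 = agent$thresholds[4],
        choice_temperature = agent$choice_temperature,
        bias_choice_coef = agent$bias_choice_coef,
        deliberation_gain = agent$deliberation_gain,
        quit_hazard_base = agent$quit_hazard_base,
        sunk_cost_strength = agent$sunk_cost_strength,
        gender = cov$gender, bmi_group = cov$bmi_group, smoker = cov$smoker)
      generate_session(agent, task, seed = NULL,
                       participant_id = sprintf("S%03d", i),
                       task_variant = task_variant, setting = setting,
                       covariates = cov,
                       include_trajectories = include_trajectories)
    })
  })
  attr(sessions, "agents") <- dplyr::bind_rows(agents)
  sessions
}

#' Simulate delay-discounting survey responses
#'
#' A hyperbolic discounter with rate `k_true` chooses the delayed option of
#' an item iff `delayed / (1 + k_true * delay) > immediate`, i.e. iff the
#' item's implied k exceeds `k_true`; responses are optionally flipped with
#' probability `noise`.
#'
#' @param k_true True hyperbolic discounting rate (1/days); `Inf` always
#'   takes the immediate option, `0` always the delayed one.
#' @param items Item bank with columns `immediate_amount`, `delayed_amount`,
#'   `delay_days` (see [load_item_bank()]).
#' @param noise Response-flip probability.
#' @param seed Optional seed.
#' @return Integer vector: 1 = chose delayed, 0 = chose immediate.
#' @export
generate_survey_responses <- function(k_true, items, noise = 0, seed = NULL) {
  stopifnot(k_true >= 0, noise >= 0, noise <= 1)
  .with_seed(seed, {
    implied <- (items$delayed_amount / items$immediate_amount - 1) / items$delay_days
    resp <- as.integer(implied > k_true)
    if (noise > 0) {
      flip <- stats::runif(length(resp)) < noise
      resp[flip] <- 1L - resp[flip]
    }
    resp
  })
}
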