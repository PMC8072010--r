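make_traj <- function(heading, t = NULL, x = NULL, y = NULL) {
  n <- length(heading)
  data.frame(t = if (is.null(t)) seq(0, by = 50, length.out = n) else t,
             x = if (is.null(x)) seq(0, 1, length.out = n) else x,
             y = if (is.null(y)) seq(0, 1, length.out = n) else y,
             heading = heading)
}

test_that("decision latency follows the version-specific convention", {
  tr <- data.frame(t_offer = c(0, 10000), t_move = c(1000, 10800),
                   t_exit = c(3700, 12000))
  expect_equal(decision_latency(tr, version = 4), c(2700, 1200))
  expect_equal(decision_latency(tr, version = 2), c(3700, 2000))
  tr$t_move[1] <- NA  # metric unavailable without first movement in v3-4
  expect_true(is.na(decision_latency(tr, version = 4)[1]))
})

test_that("reaction time exists only with a gated offer zone and a strict 15 s cut", {
  tr <- data.frame(t_offer = c(0, 0, 0), t_move = c(800, 15000, 15001),
                   t_exit = c(2000, 16000, 16001))
  expect_true(all(is.na(reaction_time(tr, version = 2))))
  expect_equal(reaction_time(tr, version = 3), c(800, 15000, 15001))
  m <- data.frame(latency_ms = c(2000, 1000, 1000),
                  rotation_deg = 10, reaction_ms = c(800, 15000, 15001))
  m <- apply_exclusions(m)
  expect_equal(m$excluded_reaction, c(FALSE, FALSE, TRUE))
})

test_that("path distance integrates Euclidean steps", {
  expect_equal(path_distance(make_traj(c(0, 0), x = c(0, 0), y = c(0, 0))), 0)
  expect_equal(path_distance(make_traj(c(0, 0), x = c(0, 3), y = c(0, 4))), 5)
  set.seed(3)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    tj <- make_traj(runif(n, 0, 360), x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
    expect_equal(path_distance(tj), oracle_distance(tj$x, tj$y),
                 tolerance = 1e-12)
  }
})

test_that("total rotation sums minimal-angle heading changes", {
  expect_equal(total_rotation(make_traj(c(45, 45, 45))), 0)
  expect_equal(total_rotation(make_traj(c(0, 90, 0))), 180)
  expect_equal(total_rotation(make_traj(c(350, 10))), 20)  # wrap at the seam
  expect_equal(total_rotation(make_traj(c(10, 350))), 20)
  expect_error(total_rotation(make_traj(c(0, 380))),
               class = "rowforage_validation_error")
  # invariances: constant heading offset (mod 360) and left/right mirror
  set.seed(4)
  h <- runif(30, 0, 360)
  base <- total_rotation(make_traj(h))
  expect_equal(total_rotation(make_traj((h + 123.4) %% 360)), base,
               tolerance = 1e-9)
  expect_equal(total_rotation(make_traj((360 - h) %% 360)), base,
               tolerance = 1e-9)
})

test_that("rotation reversals count sign changes above the jitter threshold", {
  expect_equal(rotation_reversals(make_traj(c(0, 30, 60, 90, 120))), 0)
  expect_equal(rotation_reversals(make_traj(c(0, 90, 45, 90))), 2)
  # sub-jitter wobble is ignored
  expect_equal(rotation_reversals(make_traj(c(0, 30, 29.5, 60)), jitter_deg = 1), 0)
  set.seed(6)
  for (i in 1:50) {
    h <- cumsum(rnorm(20, 0, 30)) %% 360
    expect_equal(rotation_reversals(make_traj(h)), oracle_reversals(h))
  }
})

test_that("pause time accumulates intervals without movement or rotation", {
  tj <- make_traj(rep(10, 11), t = seq(0, 500, by = 50),
                  x = rep(0.2, 11), y = rep(0.4, 11))
  expect_equal(pause_time(tj), 500)
  moving <- make_traj(rep(10, 11), t = seq(0, 500, by = 50),
                      x = seq(0, 1, length.out = 11), y = rep(0, 11))
  expect_equal(pause_time(moving), 0)
  # rotation alone breaks a pause
  turning <- make_traj(seq(0, 50, length.out = 11), t = seq(0, 500, by = 50),
                       x = rep(0, 11), y = rep(0, 11))
  expect_equal(pause_time(turning), 0)
})

test_that("pause plus moving time accounts for the full latency window", {
  s <- generate_session(agent_config(deliberation_gain = 2, thresholds = 16),
                        task_config(n_circuits = 5), seed = 17)
  m <- suppressWarnings(offer_zone_metrics(s))
  tj <- s$trajectories
  for (i in m$trial_index[1:10]) {
    g <- tj[tj$trial_index == i, ]
    window <- max(g$t) - min(g$t)
    moving <- sum(diff(g$t)) - pause_time(g)
    expect_lte(abs((pause_time(g) + moving) - window), 50)
  }
})

test_that("entry bias is a signed percentage of hallway width", {
  expect_equal(entry_bias(0), 0)
  expect_equal(entry_bias(-0.5), -50)
  expect_equal(entry_bias(0.25), 25)
  expect_equal(entry_bias(1.2, width = 4), 30)
  expect_error(entry_bias(0.6), class = "rowforage_validation_error")
})

test_that("exclusion rules differ in scope for latency and rotation", {
  m <- data.frame(latency_ms = c(16000, 5000, 14900, 3000),
                  rotation_deg = c(100, 400, 350, 360),
                  reaction_ms = NA_real_)
  m <- apply_exclusions(m)
  expect_equal(m$excluded_latency, c(TRUE, FALSE, FALSE, FALSE))
  # the >15 s trial loses everything; the 400-degree trial only rotation;
  # 360 exactly is retained ("more than 360")
  expect_equal(m$excluded_rotation, c(TRUE, TRUE, FALSE, FALSE))
  tally <- attr(m, "exclusion_tally")
  expect_equal(tally$latency, 1)
  expect_equal(tally$rotation_only, 1)
})

test_that("within-session normalization is log10 + z over retained trials", {
  v <- c(100, 300, 900, 2700, 81000)
  z <- normalize_within_session(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # log10 equal spacing: these are geometric, so z is linear in rank
  expect_equal(diff(z)[1], diff(z)[2], tolerance = 1e-9)
  # excluded trials get NA and do not shape the statistics
  z2 <- normalize_within_session(c(v, 1e9), retained = c(rep(TRUE, 5), FALSE))
  expect_true(is.na(z2[6]))
  expect_equal(z2[1:5], z, tolerance = 1e-12)
  # zeros are offset to half the smallest positive value
  z3 <- normalize_within_session(c(0, 10, 100))
  expect_equal(z3, normalize_within_session(c(5, 10, 100)), tolerance = 1e-12)
  expect_warning(zc <- normalize_within_session(rep(7, 4)), "zero variance")
  expect_equal(zc, rep(0, 4))
})

test_that("reversal counts pass through normalization untouched", {
  s <- generate_session(agent_config(), task_config(n_circuits = 4), seed = 19)
  m <- suppressWarnings(offer_zone_metrics(s))
  expect_true(is.integer(m$n_reversals))
  expect_false("z_reversals" %in% names(m))
  expect_true(all(c("z_latency", "z_rotation", "z_pause", "z_distance",
                    "z_reaction") %in% names(m)))
  ok <- !m$excluded_latency
  expect_equal(mean(m$z_latency[ok]), 0, tolerance = 1e-9)
  expect_equal(sd(m$z_latency[ok]), 1, tolerance = 1e-9)
})

test_that("value tuning returns per-participant slopes and a cohort summary", {
  set.seed(8)
  d <- do.call(rbind, lapply(1:12, function(p) {
    value <- runif(30, -10, 10)
    data.frame(participant_id = sprintf("P%02d", p), value = value,
               z_latency = -0.2 * abs(value) + rnorm(30, 0, 0.3))
  }))
  vt <- value_tuning(d)
  expect_equal(nrow(vt$slopes), 12)
  expect_lt(vt$summary$mean_slope, 0)
  expect_lt(vt$summary$ci_hi, 0)
  # constant z has exactly zero slope
  d0 <- data.frame(participant_id = "a", value = runif(20, -5, 5),
                   z_latency = 1)
  expect_equal(value_tuning(d0)$slopes$slope, 0)
  # bins are centered so one bin contains value 0
  expect_true(0 %in% vt$curve$bin)
})
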