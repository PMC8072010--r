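# Minimal-angle wrap of heading differences to (-180, 180]; any other
# convention inflates rotation at the 0/360 seam.
.wrap_deg <- function(d) {
  w <- ((d + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

.check_traj <- function(trajectory, min_samples = 2) {
  stopifnot(is.data.frame(trajectory))
  if (nrow(trajectory) < min_samples)
    rlang::abort(sprintf("trajectory needs at least %d samples", min_samples))
  trajectory
}

#' Decision latency: time spent in the offer zone
#'
#' Versions 1-2 measure from offer presentation (`t_exit - t_offer`);
#' versions 3-4, where a gate holds the avatar until the offer appears,
#' measure from first movement (`t_exit - t_move`). Trials missing `t_move`
#' in versions 3-4 get `NA` (metric unavailable).
#'
#' @param trials Trial table of a session.
#' @param version Task version 1-4.
#' @return Latency in ms per trial.
#' @export
decision_latency <- function(trials, version) {
  if (version >= 3) as.numeric(trials$t_exit - trials$t_move)
  else as.numeric(trials$t_exit - trials$t_offer)
}

#' Reaction time: offer presentation to first movement
#'
#' Only versions 3-4 record first movement. Values are returned raw; trials
#' exceeding 15 s (strictly) are flagged for exclusion by
#' [apply_exclusions()].
#'
#' @param trials Trial table.
#' @param version Task version; below 3 the measure is unavailable (all
#'   `NA`).
#' @return Reaction time in ms per trial.
#' @export
reaction_time <- function(trials, version) {
  if (version < 3) return(rep(NA_real_, nrow(trials)))
  as.numeric(trials$t_move - trials$t_offer)
}

#' Integrated path distance within the offer zone
#'
#' Sum of Euclidean distances between consecutive position samples, in the
#' task's arbitrary track units.
#'
#' @param trajectory Data frame with `x`, `y` (and any other columns).
#' @return Total distance.
#' @export
path_distance <- function(trajectory) {
  .check_traj(trajectory)
  sum(sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2))
}

#' Total rotation (IdPhi-style integrated angular change)
#'
#' Sum of absolute heading changes across consecutive samples, with each
#' change wrapped to the minimal angle in (-180, 180]. This is the
#' virtual-navigation analogue of the rodent VTE measure IdPhi.
#'
#' @param trajectory Data frame with a `heading` column in degrees
#'   \[0, 360).
#' @return Total rotation in degrees.
#' @export
total_rotation <- function(trajectory) {
  .check_traj(trajectory)
  h <- trajectory$heading
  if (any(h < 0 | h >= 360, na.rm = TRUE))
    rlang::abort("heading outside [0, 360)", class = "rowforage_validation_error")
  sum(abs(.wrap_deg(diff(h))))
}

#' Count reversals of rotation direction
#'
#' Counts sign changes in the sequence of wrapped heading increments, after
#' discarding increments smaller than `jitter_deg` in magnitude (raw sign
#' changes over-count on noisy logs).
#'
#' @param trajectory Data frame with `heading`.
#' @param jitter_deg Increments with `|delta| < jitter_deg` are ignored.
#' @return Number of direction reversals.
#' @export
rotation_reversals <- function(trajectory, jitter_deg = 1) {
  .check_traj(trajectory, min_samples = 3)
  d <- .wrap_deg(diff(trajectory$heading))
  d <- d[abs(d) >= jitter_deg]
  if (length(d) < 2) return(0L)
  sum(diff(sign(d)) != 0)
}

#' Cumulative pause time within the offer zone
#'
#' Total time over inter-sample intervals in which the participant neither
#' moved (displacement below `move_eps`) nor rotated (absolute wrapped
#' heading change below `jitter_deg`) — an exact-equality reading with a
#' float tolerance.
#'
#' @param trajectory Data frame with `t` (ms), `x`, `y`, `heading`.
#' @param move_eps Displacement tolerance in track units.
#' @param jitter_deg Heading-change tolerance in degrees.
#' @return Paused time in ms.
#' @export
pause_time <- function(trajectory, move_eps = 1e-6, jitter_deg = 1) {
  .check_traj(trajectory)
  disp <- sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2)
  dh <- abs(.wrap_deg(diff(trajectory$heading)))
  still <- disp < move_eps & dh < jitter_deg
  sum(diff(trajectory$t)[still])
}

#' Entry bias as a signed percentage of hallway width
#'
#' The lateral position on entering the offer zone, relative to the hallway
#' center (bias 0), scaled to the hallway width: -50% is at the wall toward
#' the participant's left and the reward location, +50% at the wall toward
#' the right and the exit used to skip.
#'
#' @param entry_position Signed offset from center (same units as `width`).
#' @param width Hallway width (default 1, for offsets already expressed as a
#'   fraction of width).
#' @return Percentage in \[-50, 50\].
#' @export
entry_bias <- function(entry_position, width = 1) {
  pct <- 100 * entry_position / width
  if (any(abs(pct) > 50 + 1e-9, na.rm = TRUE))
    rlang::abort("entry offset exceeds half the hallway width",
                 class = "rowforage_validation_error")
  pct
}

#' Per-trial offer-zone behavioral measures for a session
#'
#' Computes decision latency, reaction time (versions 3-4), integrated
#' distance, total rotation, rotation reversals, pause time and entry bias
#' for every trial, applies the exclusion rules ([apply_exclusions()]) and
#' the within-session normalization ([normalize_metrics()]).
#'
#' @param session A `row_session`.
#' @param jitter_deg Heading jitter threshold for reversals and pausing.
#' @param move_eps Displacement tolerance for pausing.
#' @param latency_max_ms,rotation_max_deg Exclusion bounds (see
#'   [apply_exclusions()]).
#' @return A tibble with raw measures, exclusion flags and z-scored columns;
#'   the exclusion tally is attached as `attr(, "exclusion_tally")`.
#' @export
offer_zone_metrics <- function(session, jitter_deg = 1, move_eps = 1e-6,
                               latency_max_ms = 15000, rotation_max_deg = 360) {
  stopifnot(inherits(session, "row_session"))
  tr <- session$trials
  tj <- session$trajectories
  n <- nrow(tr)
  distance <- rotation <- pause <- rep(NA_real_, n)
  reversals <- rep(NA_integer_, n)
  if (nrow(tj) > 1) {
    if (any(tj$heading < 0 | tj$heading >= 360, na.rm = TRUE))
      rlang::abort("heading outside [0, 360)",
                   class = "rowforage_validation_error")
    # All per-trial sums computed in one pass over consecutive sample pairs,
    # masking pairs that straddle a trial boundary.
    lev <- factor(tr$trial_index)
    ti <- tj$trial_index
    ns <- nrow(tj)
    same <- ti[-1] == ti[-ns]
    step <- sqrt(diff(tj$x)^2 + diff(tj$y)^2)
    dh <- .wrap_deg(diff(tj$heading))
    dt <- diff(tj$t)
    grp <- factor(ti[-1], levels = levels(lev))
    n_samp <- tabulate(factor(ti, levels = levels(lev)), nbins = n)
    sum_by <- function(v, keep) {
      out <- rep(0, n)
      if (any(keep)) {
        rs <- rowsum(v[keep], grp[keep])
        out[match(rownames(rs), levels(lev))] <- rs[, 1]
      }
      out
    }
    still <- step < move_eps & abs(dh) < jitter_deg
    distance <- sum_by(step, same)
    rotation <- sum_by(abs(dh), same)
    pause <- sum_by(as.numeric(dt), same & still)
    keep <- same & abs(dh) >= jitter_deg
    sgn <- sign(dh)[keep]
    gk <- as.integer(grp[keep])
    flip <- if (length(sgn) > 1)
      sgn[-1] != sgn[-length(sgn)] & gk[-1] == gk[-length(gk)] else logical(0)
    rev_count <- rep(0L, n)
    if (any(flip)) {
      rs <- rowsum(rep(1L, sum(flip)), gk[-1][flip])
      rev_count[as.integer(rownames(rs))] <- rs[, 1]
    }
    reversals <- rev_count
    distance[n_samp < 2] <- NA_real_
    rotation[n_samp < 2] <- NA_real_
    pause[n_samp < 2] <- NA_real_
    reversals[n_samp < 3] <- NA_integer_
  }
  m <- tibble::tibble(participant_id = session$participant_id,
                      trial_index = tr$trial_index, category = tr$category,
                      offered_delay = tr$offered_delay, decision = tr$decision,
                      latency_ms = decision_latency(tr, session$version),
                      reaction_ms = reaction_time(tr, session$version),
                      distance = distance, rotation_deg = rotation,
                      n_reversals = reversals, pause_ms = pause,
                      entry_bias_pct = entry_bias(tr$entry_position),
                      entry_position = tr$entry_position)
  m <- apply_exclusions(m, latency_max_ms = latency_max_ms,
                        rotation_max_deg = rotation_max_deg)
  normalize_metrics(m)
}

#' Apply the offer-zone exclusion rules
#'
#' Decision latencies longer than 15 s remove the trial from all offer-zone
#' measures; rotation exceeding 360 degrees removes the rotation measures
#' (total rotation and reversals) only. Reaction times exceeding 15 s are
#' excluded from the reaction measure. All bounds are strict ("longer
#' than" / "exceeded").
#'
#' @param metrics Per-trial metrics (from [offer_zone_metrics()] before
#'   flags).
#' @param latency_max_ms,rotation_max_deg,reaction_max_ms Exclusion bounds.
#' @return `metrics` with logical `excluded_latency`, `excluded_rotation`,
#'   `excluded_reaction` columns and an `"exclusion_tally"` attribute
#'   (`list(latency, rotation_only, reaction)`).
#' @export
apply_exclusions <- function(metrics, latency_max_ms = 15000,
                             rotation_max_deg = 360,
                             reaction_max_ms = 15000) {
  lat_bad <- !is.na(metrics$latency_ms) & metrics$latency_ms > latency_max_ms
  rot_over <- !is.na(metrics$rotation_deg) & metrics$rotation_deg > rotation_max_deg
  rea_bad <- !is.na(metrics$reaction_ms) & metrics$reaction_ms > reaction_max_ms
  metrics$excluded_latency <- lat_bad
  metrics$excluded_rotation <- lat_bad | rot_over
  metrics$excluded_reaction <- lat_bad | rea_bad
  attr(metrics, "exclusion_tally") <- list(latency = sum(lat_bad),
                                           rotation_only = sum(rot_over & !lat_bad),
                                           reaction = sum(rea_bad & !lat_bad))
  metrics
}

#' Log10 + z-score normalization within a session
#'
#' Offer-zone measures carry a strong positive skew, so retained values are
#' log10-transformed and then z-scored within the session. Zeros are offset
#' to half the smallest positive retained value before the log. A
#' zero-variance session yields all-zero z with a warning. Rotation reversal
#' counts are never normalized.
#'
#' @param values Numeric vector of one measure across a session's trials.
#' @param retained Logical vector: trials entering the normalization;
#'   excluded trials get `NA`.
#' @param log10_transform Apply the log10 step (default).
#' @return z-scores, `NA` outside `retained`.
#' @export
normalize_within_session <- function(values, retained = !is.na(values),
                                     log10_transform = TRUE) {
  retained <- retained & !is.na(values)
  z <- rep(NA_real_, length(values))
  v <- values[retained]
  if (length(v) == 0) return(z)
  if (log10_transform) {
    if (any(v < 0))
      rlang::abort("negative values cannot be log-transformed")
    if (any(v == 0)) {
      pos <- v[v > 0]
      offset <- if (length(pos) > 0) min(pos) / 2 else 1
      v[v == 0] <- offset
    }
    v <- log10(v)
  }
  s <- stats::sd(v)
  if (length(v) < 2 || is.na(s) || s == 0) {
    rlang::warn("zero variance within session; z-scores set to 0")
    z[retained] <- 0
    return(z)
  }
  z[retained] <- (v - mean(v)) / s
  z
}

#' Add within-session z-scored measures to a metrics table
#'
#' @param metrics Output of [apply_exclusions()].
#' @return `metrics` with `z_latency`, `z_distance`, `z_rotation`, `z_pause`,
#'   `z_reaction` columns (reversal counts are left untransformed).
#' @export
normalize_metrics <- function(metrics) {
  ok <- !metrics$excluded_latency
  norm <- function(v, retained) {
    if (all(is.na(v[retained]))) return(rep(NA_real_, length(v)))
    normalize_within_session(v, retained)
  }
  metrics$z_latency <- norm(metrics$latency_ms, ok)
  metrics$z_distance <- norm(metrics$distance, ok)
  metrics$z_pause <- norm(metrics$pause_ms, ok)
  metrics$z_rotation <- norm(metrics$rotation_deg, !metrics$excluded_rotation)
  metrics$z_reaction <- norm(metrics$reaction_ms, !metrics$excluded_reaction)
  metrics
}

#' Value tuning of a normalized measure
#'
#' Quantifies how a z-scored offer-zone measure varies with offer value
#' (threshold minus delay): per participant, binned means over value and an
#' ordinary least-squares slope of z on |value| (deliberation predicts a
#' negative slope — more time and motion as value approaches 0); across the
#' cohort, the mean slope with a t-based confidence interval, and the
#' across-participant mean binned curve.
#'
#' @param data Data frame with `participant_id`, `value` and a z-metric
#'   column named by `metric`.
#' @param metric Name of the z-metric column.
#' @param bin_width Value bin width in seconds (bins are centered so one bin
#'   contains value 0).
#' @param min_trials Minimum value-labeled trials per participant.
#' @param min_bin_trials Minimum trials for a participant's bin mean.
#' @param conf Confidence level for the cohort slope interval.
#' @return A list of class `value_tuning`: `slopes` (per participant),
#'   `binned` (participant x bin), `curve` (cohort bin means with
#'   participant counts), `summary` (mean slope, CI, t-test p).
#' @export
value_tuning <- function(data, metric = "z_latency", bin_width = 2,
                         min_trials = 10, min_bin_trials = 3, conf = 0.95) {
  stopifnot(all(c("participant_id", "value", metric) %in% names(data)))
  d <- data[!is.na(data$value) & !is.na(data[[metric]]), , drop = FALSE]
  d$z <- d[[metric]]
  d$abs_value <- abs(d$value)
  d$bin <- round(d$value / bin_width) * bin_width
  keep <- names(which(table(d$participant_id) >= min_trials))
  d <- d[d$participant_id %in% keep, , drop = FALSE]
  if (nrow(d) == 0)
    rlang::abort("no participants with enough value-labeled trials")

  slopes <- dplyr::summarise(
    dplyr::group_by(d, .data$participant_id),
    slope = {
      if (stats::var(.data$abs_value) == 0) 0
      else stats::cov(.data$z, .data$abs_value) / stats::var(.data$abs_value)
    },
    n = dplyr::n(), .groups = "drop")

  binned <- dplyr::summarise(
    dplyr::group_by(d, .data$participant_id, .data$bin),
    mean_z = mean(.data$z), n = dplyr::n(), .groups = "drop")
  binned <- binned[binned$n >= min_bin_trials, , drop = FALSE]

  curve <- dplyr::summarise(
    dplyr::group_by(binned, .data$bin),
    mean_z = mean(.data$mean_z), n_participants = dplyr::n(),
    .groups = "drop")

  s <- slopes$slope
  np <- length(s)
  if (np >= 2) {
    se <- stats::sd(s) / sqrt(np)
    tq <- stats::qt(1 - (1 - conf) / 2, df = np - 1)
    p <- if (stats::sd(s) > 0) stats::t.test(s)$p.value else NA_real_
  } else {
    se <- tq <- p <- NA_real_
  }
  summary <- tibble::tibble(n_participants = np, mean_slope = mean(s),
                            se = se, ci_lo = mean(s) - tq * se,
                            ci_hi = mean(s) + tq * se, p_value = p)
  structure(list(slopes = slopes, binned = binned, curve = curve,
                 summary = summary, metric = metric, bin_width = bin_width),
            class = "value_tuning")
}

#' @export
print.value_tuning <- function(x, ...) {
  cat(sprintf("<value_tuning> %s, %g s bins\n", x$metric, x$bin_width))
  print(x$summary)
  invisible(x)
}

#' Location of the peak of a cohort value-tuning curve
#'
#' @param tuning A [value_tuning()] result.
#' @param min_participants Bins supported by fewer participants are ignored.
#' @return The bin center (s) with the maximal cohort mean.
#' @export
tuning_peak <- function(tuning, min_participants = 5) {
  stopifnot(inherits(tuning, "value_tuning"))
  cv <- tuning$curve[tuning$curve$n_participants >= min_participants, ,
                     drop = FALSE]
  if (nrow(cv) == 0) return(NA_real_)
  cv$bin[which.max(cv$mean_z)]
}
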