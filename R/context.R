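# Trials are visited in track order, so the "previous zone" is simply the
# immediately preceding trial.
.skipish <- function(decision, quit_as_skip = TRUE) {
  if (quit_as_skip) decision %in% c("skip", "quit") else decision == "skip"
}

#' Label regret-inducing and control trials
#'
#' A trial is regret-inducing when the current offer is poor (above the delay
#' threshold) and the participant skipped or quit a good (below-threshold)
#' offer at the previous zone — a low-quality offer received after passing up
#' a higher-quality one. Control-1: the current offer is poor and the
#' previous good offer was accepted. Control-2: the current offer is poor and
#' the previous offer was itself poor and was skipped or quit. All other
#' trials (including every good-offer trial, and trials whose own or previous
#' value is unavailable) are `"none"`.
#'
#' @param trials Data frame in trial order with columns `decision` and
#'   `value_type` (`"good"` / `"poor"` / `"boundary"` / `NA`).
#' @param quit_as_skip Treat quits as rejections (default, matching the
#'   stay = 1 / skip-or-quit = 0 coding).
#' @return Character vector: `"regret"`, `"control1"`, `"control2"`,
#'   `"none"`.
#' @export
label_regret <- function(trials, quit_as_skip = TRUE) {
  n <- nrow(trials)
  out <- rep("none", n)
  if (n < 2) return(out)
  cur_v <- trials$value_type
  prev_v <- c(NA, cur_v[-n])
  prev_d <- c(NA, trials$decision[-n])
  prev_rejected <- !is.na(prev_d) & .skipish(prev_d, quit_as_skip)
  prev_stayed <- !is.na(prev_d) & prev_d == "stay"
  poor_now <- !is.na(cur_v) & cur_v == "poor"
  prev_good <- !is.na(prev_v) & prev_v == "good"
  prev_poor <- !is.na(prev_v) & prev_v == "poor"
  out[poor_now & prev_good & prev_rejected] <- "regret"
  out[poor_now & prev_good & prev_stayed] <- "control1"
  out[poor_now & prev_poor & prev_rejected] <- "control2"
  out
}

#' Label sequential-choice cells
#'
#' Each trial after the first is assigned the cell (decision on trial i-1,
#' decision on trial i), with quits grouped with skips by default. The first
#' trial is `"undefined"`; with `quit_as_skip = FALSE`, pairs involving a
#' quit are `"undefined"` too.
#'
#' @inheritParams label_regret
#' @return Character vector in `{"skip_skip", "skip_stay", "stay_skip",
#'   "stay_stay", "undefined"}`.
#' @export
label_sequence <- function(trials, quit_as_skip = TRUE) {
  n <- nrow(trials)
  d <- trials$decision
  if (quit_as_skip) d[d == "quit"] <- "skip"
  cell <- rep("undefined", n)
  if (n < 2) return(cell)
  prev <- c(NA, d[-n])
  ok <- !is.na(prev) & prev %in% c("skip", "stay") & d %in% c("skip", "stay")
  cell[ok] <- paste(prev[ok], d[ok], sep = "_")
  cell
}

#' Label a trial table with economic context
#'
#' Combines [label_regret()], [label_sequence()] and a preference-override
#' flag (accepting a poor offer or rejecting a good one).
#'
#' @inheritParams label_regret
#' @return A tibble with `trial_index`, `regret_class`, `sequence_cell`,
#'   `override`.
#' @export
label_context <- function(trials, quit_as_skip = TRUE) {
  v <- trials$value_type
  override <- (!is.na(v) & v == "poor" & trials$decision == "stay") |
    (!is.na(v) & v == "good" & .skipish(trials$decision, quit_as_skip))
  tibble::tibble(trial_index = trials$trial_index,
                 regret_class = label_regret(trials, quit_as_skip),
                 sequence_cell = label_sequence(trials, quit_as_skip),
                 override = override)
}

#' Compare a measure between two economic contexts
#'
#' Computes participant-level means of a (typically z-scored) measure for two
#' context cells, then a Wilcoxon signed-rank test across participants.
#' Participants missing either cell are dropped from the pair (and reported).
#' If a `decision` column is present, per-cell acceptance probabilities are
#' summarized too (for the regret contrast: how likely participants are to
#' accept low-value offers in each condition).
#'
#' @param data Per-trial data frame with `participant_id`, a label column, a
#'   metric column, and optionally `decision`.
#' @param cells Length-2 character vector of cell labels to contrast.
#' @param metric Name of the metric column.
#' @param label_col Name of the label column (e.g. `"regret_class"` or
#'   `"sequence_cell"`).
#' @param min_participants Minimum participants contributing both cells.
#' @return A list of class `context_contrast`: `cells`, `participant_means`,
#'   `means`, `p_value` (Wilcoxon signed-rank), `n_participants`,
#'   `n_dropped`, `acceptance` (or `NULL`).
#' @export
compare_contexts <- function(data, cells, metric = "z_latency",
                             label_col = "regret_class",
                             min_participants = 5) {
  stopifnot(length(cells) == 2,
            all(c("participant_id", label_col, metric) %in% names(data)))
  d <- data[data[[label_col]] %in% cells & !is.na(data[[metric]]), , drop = FALSE]
  d$cell <- d[[label_col]]
  d$metric_value <- d[[metric]]
  pm <- dplyr::summarise(
    dplyr::group_by(d, .data$participant_id, .data$cell),
    mean_value = mean(.data$metric_value), n = dplyr::n(), .groups = "drop")
  wide <- merge(pm[pm$cell == cells[1], c("participant_id", "mean_value")],
                pm[pm$cell == cells[2], c("participant_id", "mean_value")],
                by = "participant_id", suffixes = c("_1", "_2"))
  n_dropped <- length(unique(pm$participant_id)) - nrow(wide)
  if (nrow(wide) < min_participants)
    rlang::abort(sprintf(
      "insufficient participants with both '%s' and '%s' trials (%d < %d)",
      cells[1], cells[2], nrow(wide), min_participants),
      class = "rowforage_data_error")
  test <- stats::wilcox.test(wide$mean_value_1, wide$mean_value_2,
                             paired = TRUE, exact = FALSE)
  acceptance <- NULL
  if ("decision" %in% names(d)) {
    acc <- dplyr::summarise(
      dplyr::group_by(d, .data$participant_id, .data$cell),
      p_accept = mean(.data$decision == "stay"), .groups = "drop")
    acceptance <- dplyr::summarise(dplyr::group_by(acc, .data$cell),
                                   p_accept = mean(.data$p_accept),
                                   n_participants = dplyr::n(),
                                   .groups = "drop")
  }
  structure(list(cells = cells, metric = metric,
                 participant_means = tibble::as_tibble(wide),
                 means = stats::setNames(c(mean(wide$mean_value_1),
                                           mean(wide$mean_value_2)), cells),
                 p_value = test$p.value, n_participants = nrow(wide),
                 n_dropped = n_dropped, acceptance = acceptance),
            class = "context_contrast")
}

#' @export
print.context_contrast <- function(x, ...) {
  cat(sprintf("<context_contrast> %s: %s vs %s\n", x$metric, x$cells[1],
              x$cells[2]))
  cat(sprintf("  means: %.3f vs %.3f; Wilcoxon p = %.4g (n = %d, dropped %d)\n",
              x$means[1], x$means[2], x$p_value, x$n_participants,
              x$n_dropped))
  invisible(x)
}
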