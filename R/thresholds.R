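#' Extract stay/skip choice points from a session
#'
#' Stays code 1; skips and quits code 0 (a quit is a rejection of the offer's
#' delay, discovered late).
#'
#' @param session A `row_session` (or its trial table).
#' @return A tibble with `category`, `trial_index`, `delay`, `choice`.
#' @export
choice_points <- function(session) {
  trials <- if (inherits(session, "row_session")) session$trials else session
  tibble::tibble(category = trials$category,
                 trial_index = trials$trial_index,
                 delay = trials$offered_delay,
                 choice = as.integer(trials$decision == "stay"))
}

#' Pad a choice series for Heaviside fitting
#'
#' Adds one synthetic stay at 1 s less than the minimum delay offered and one
#' synthetic skip at 1 s longer than the maximum, so that all-accept and
#' all-reject series still admit a step fit. Synthetic points are flagged
#' (`padded = TRUE`) and are never treated as real trials downstream; padding
#' an already-padded series is an error.
#'
#' @param points Data frame with columns `delay`, `choice` (and optionally
#'   `trial_index`).
#' @return The input plus exactly two flagged synthetic points.
#' @export
pad_choices <- function(points) {
  points <- as.data.frame(points)
  if (nrow(points) < 1)
    rlang::abort("cannot pad an empty choice series")
  if ("padded" %in% names(points) && any(points$padded))
    rlang::abort("choice series is already padded")
  points$padded <- FALSE
  if (!"trial_index" %in% names(points)) points$trial_index <- NA_integer_
  pads <- data.frame(delay = c(min(points$delay) - 1, max(points$delay) + 1),
                     choice = c(1L, 0L), padded = TRUE,
                     trial_index = NA_integer_)
  for (col in setdiff(names(points), names(pads))) pads[[col]] <- points[[col]][1][NA]
  rbind(points, pads[names(points)])
}

#' Fit a Heaviside step function to padded choices
#'
#' Finds the threshold minimizing the number of points where the prediction
#' "stay iff delay < threshold" disagrees with the observed choice. Candidate
#' thresholds are the midpoints between consecutive sorted unique delays;
#' among error ties the mean of all minimizing candidates is returned (a
#' symmetric, deterministic tie-break). The threshold is the point at which
#' the participant is equally likely to stay or skip.
#'
#' @param points A padded choice series from [pad_choices()].
#' @return A list with `threshold` (s) and `error` (misclassified count).
#' @export
fit_heaviside <- function(points) {
  if (!"padded" %in% names(points) || !any(points$padded))
    rlang::abort("fit_heaviside() expects a padded series; see pad_choices()")
  .fit_step(points$delay, points$choice)
}

# Core step fit; delays need not be unique. The prediction is "stay iff
# delay < threshold", so between consecutive unique delays the error count
# is constant: with points sorted by delay, the error at a candidate above
# the j-th unique delay is (#stays above it) + (#skips at or below it),
# computed from cumulative counts.
.fit_step <- function(delay, choice) {
  o <- order(delay)
  d <- delay[o]
  ch <- choice[o]
  nd <- length(d)
  is_last <- c(d[-1] != d[-nd], TRUE)
  u <- d[is_last]
  K <- length(u)
  if (K < 2) {
    # degenerate: one distinct delay; the step can only sit on either side
    cand <- c(u - 0.5, u + 0.5)
    err <- c(sum(ch == 1L), sum(ch == 0L))
  } else {
    cum1 <- cumsum(ch)[is_last]
    cum0 <- cumsum(1L - ch)[is_last]
    err <- (cum1[K] - cum1[-K]) + cum0[-K]
    cand <- (u[-K] + u[-1]) / 2
  }
  best <- err == min(err)
  list(threshold = mean(cand[best]), error = min(err))
}

#' Leave-one-out trial-specific thresholds
#'
#' For each real trial, a threshold is fitted to every other offer of the same
#' reward type (re-padded within each subset), yielding a trial-specific
#' threshold that is independent of the held-out choice; the participant's
#' overall threshold is the arithmetic mean of these. The inverse fit (the
#' same procedure on the inverted choices) is computed alongside for response
#' -pattern classification.
#'
#' @param points Unpadded choice series for one participant and category:
#'   columns `delay`, `choice`, and optionally `trial_index`.
#' @return A tibble with one row per real trial: `trial_index`, `delay`,
#'   `choice`, `loo_threshold`, `loo_error`, `loo_inverse_error`.
#' @export
loo_thresholds <- function(points) {
  points <- as.data.frame(points)
  if ("padded" %in% names(points)) points <- points[!points$padded, , drop = FALSE]
  n <- nrow(points)
  if (n < 2)
    rlang::abort("leave-one-out thresholds require at least 2 real trials")
  if (!"trial_index" %in% names(points)) points$trial_index <- seq_len(n) - 1L
  delay <- points$delay
  choice <- as.integer(points$choice)
  res <- lapply(seq_len(n), function(i) {
    d <- delay[-i]
    ch <- choice[-i]
    pd <- c(d, min(d) - 1, max(d) + 1)
    fwd <- .fit_step(pd, c(ch, 1L, 0L))
    inv <- .fit_step(pd, c(1L - ch, 1L, 0L))
    c(fwd$threshold, fwd$error, inv$error)
  })
  m <- do.call(rbind, res)
  tibble::as_tibble(data.frame(
    trial_index = points$trial_index, delay = points$delay,
    choice = points$choice, loo_threshold = m[, 1],
    loo_error = m[, 2], loo_inverse_error = m[, 3]))
}

#' Classify a participant's response pattern for one reward type
#'
#' A reward type has a normal delay threshold if the mean Heaviside fit error
#' is lower than that of the inverse fit; a long-delay preference if higher.
#' When the errors tie (the all-accept / all-reject regime), the type is
#' full-stay if at least 75% of offers were accepted, full-skip if at least
#' 75% were skipped, and otherwise unclassified (lacking a delay threshold).
#'
#' @param forward_error,inverse_error Mean misclassified counts of the
#'   forward and inverse fits (leave-one-out means).
#' @param prop_accepted Fraction of real offers accepted.
#' @param tol Numeric tolerance for the error tie.
#' @return One of `"normal"`, `"long_delay_pref"`, `"full_stay"`,
#'   `"full_skip"`, `"unclassified"`.
#' @export
classify_pattern <- function(forward_error, inverse_error, prop_accepted,
                             tol = 1e-9) {
  stopifnot(length(forward_error) == length(inverse_error),
            length(forward_error) == length(prop_accepted))
  out <- character(length(forward_error))
  tie <- abs(forward_error - inverse_error) <= tol
  out[!tie & forward_error < inverse_error] <- "normal"
  out[!tie & forward_error > inverse_error] <- "long_delay_pref"
  out[tie & prop_accepted >= 0.75] <- "full_stay"
  out[tie & prop_accepted <= 0.25] <- "full_skip"
  out[out == ""] <- "unclassified"
  out
}

#' Offer value relative to the trial-specific threshold
#'
#' Value is threshold minus offered delay: positive values are
#' better-than-threshold ("good") offers, negative are "poor", and value 0 is
#' the maximally difficult boundary offer. Values are only defined for reward
#' types with a normal delay threshold.
#'
#' @param offered_delay Offer delay (s).
#' @param loo_threshold Trial-specific (leave-one-out) threshold (s).
#' @param pattern Response pattern of the reward type; anything but
#'   `"normal"` marks the value unavailable.
#' @return A tibble with `value`, `value_type` (`"good"`, `"poor"`,
#'   `"boundary"` or `NA`), `abs_value`.
#' @export
offer_value <- function(offered_delay, loo_threshold,
                        pattern = "normal") {
  n <- max(length(offered_delay), length(loo_threshold))
  offered_delay <- rep_len(offered_delay, n)
  loo_threshold <- rep_len(loo_threshold, n)
  pattern <- rep_len(pattern, n)
  value <- loo_threshold - offered_delay
  value[pattern != "normal"] <- NA_real_
  value_type <- rep(NA_character_, n)
  value_type[!is.na(value) & value > 0] <- "good"
  value_type[!is.na(value) & value < 0] <- "poor"
  value_type[!is.na(value) & value == 0] <- "boundary"
  tibble::as_tibble(data.frame(value = value, value_type = value_type,
                               abs_value = abs(value)))
}

#' Fit per-category delay thresholds for a session
#'
#' Runs the padded leave-one-out Heaviside procedure per reward category:
#' trial-specific thresholds, the overall threshold (their mean), forward and
#' inverse mean fit errors, the response-pattern class, and per-trial offer
#' values. Categories with fewer than 2 real trials are forced to
#' `"unclassified"`.
#'
#' @param session A `row_session`, or a choice-point data frame with columns
#'   `category`, `trial_index`, `delay`, `choice` (see [choice_points()]).
#' @return An object of class `threshold_fit`: a list with `summary` (one row
#'   per category: `overall_threshold`, `forward_error`, `inverse_error`,
#'   `prop_accepted`, `pattern`, `n_trials`) and `trials` (per-trial
#'   `loo_threshold`, `value`, `value_type`, `abs_value`).
#' @export
fit_thresholds <- function(session) {
  pts <- if (is.data.frame(session) &&
             all(c("category", "delay", "choice") %in% names(session)))
    session else choice_points(session)
  pid <- if (inherits(session, "row_session")) session$participant_id else NA_character_
  summaries <- list()
  trials <- list()
  for (cat in unique(pts$category)) {
    p <- pts[pts$category == cat, , drop = FALSE]
    if (nrow(p) < 2) {
      summaries[[cat]] <- data.frame(
        participant_id = pid, category = cat, n_trials = nrow(p),
        overall_threshold = NA_real_, forward_error = NA_real_,
        inverse_error = NA_real_, prop_accepted = mean(p$choice),
        pattern = "unclassified")
      trials[[cat]] <- data.frame(
        participant_id = pid, category = cat, trial_index = p$trial_index,
        delay = p$delay, choice = p$choice, loo_threshold = NA_real_,
        value = NA_real_, value_type = NA_character_, abs_value = NA_real_)
      next
    }
    loo <- loo_thresholds(p)
    fwd <- mean(loo$loo_error)
    inv <- mean(loo$loo_inverse_error)
    prop <- mean(p$choice)
    pattern <- classify_pattern(fwd, inv, prop)
    vals <- offer_value(loo$delay, loo$loo_threshold, pattern)
    summaries[[cat]] <- data.frame(
      participant_id = pid, category = cat, n_trials = nrow(p),
      overall_threshold = mean(loo$loo_threshold), forward_error = fwd,
      inverse_error = inv, prop_accepted = prop, pattern = pattern)
    trials[[cat]] <- data.frame(
      participant_id = pid, category = cat, trial_index = loo$trial_index,
      delay = loo$delay, choice = loo$choice,
      loo_threshold = loo$loo_threshold, value = vals$value,
      value_type = vals$value_type, abs_value = vals$abs_value)
  }
  out <- list(summary = tibble::as_tibble(dplyr::bind_rows(summaries)),
              trials = tibble::as_tibble(
                dplyr::arrange(dplyr::bind_rows(trials), .data$trial_index)))
  class(out) <- "threshold_fit"
  out
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat("<threshold_fit>\n")
  print(x$summary)
  invisible(x)
}
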