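# Weighted least-squares slope of y on x with weights w (closed form).
.wls_slope <- function(x, y, w) {
  sw <- sum(w)
  if (sw <= 0 || length(unique(x[w > 0])) < 2) return(NA_real_)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
}

#' Conditional delay-completion curves (sunk-cost analysis)
#'
#' For each investment level T, selects the trials in which the delay was
#' started and at least T seconds were waited (with more than T seconds
#' initially on offer), and computes the percentage completed as a function
#' of the time remaining (delay minus T). A flattening of the
#' completion-vs-remaining slope with growing T is the sunk-cost signature:
#' once time has been invested, completion becomes insensitive to what is
#' left to wait. Slopes come from a weighted least-squares fit of completion
#' probability on remaining time; confidence intervals from a
#' participant-level bootstrap (percentile method).
#'
#' @param trials Data frame with `participant_id`, `offered_delay` (s),
#'   `decision` (`"stay"` completes the delay, `"quit"` abandons it) and
#'   `waited_s`. Trials that never started the delay (skips) are ignored.
#'   Non-integer delays are rounded to the nearest second for binning.
#' @param investments Investment levels T in seconds.
#' @param remaining_max Optional cap on the remaining time entering the
#'   slope fit and curves. Comparing slopes across investments on a common
#'   remaining-time support removes a range confound (at low investments the
#'   curve extends to long remainders where it flattens, mechanically
#'   shrinking the fitted slope).
#' @param bootstrap Number of participant-level bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @param aggregate `"pooled"` pools trials across participants (default);
#'   `"participant_mean"` averages per-participant completion proportions.
#' @return An object of class `completion_curves`: `curves` (invested,
#'   remaining, n, n_complete, p_complete), `slopes` (invested, slope,
#'   ci_lo, ci_hi, n_trials) and `slope_diffs` (pairwise slope differences
#'   between investment levels with bootstrap CIs from shared resamples —
#'   the appropriate interval for asking whether two investments'
#'   completion slopes are distinguishable).
#' @export
completion_curves <- function(trials, investments = c(0, 5, 10),
                              remaining_max = NULL, bootstrap = 2000,
                              conf = 0.95, seed = NULL,
                              aggregate = c("pooled", "participant_mean")) {
  aggregate <- match.arg(aggregate)
  started <- trials$decision %in% c("stay", "quit")
  d <- trials[started, , drop = FALSE]
  d$delay_r <- round(d$offered_delay)
  d$completed <- d$decision == "stay"
  alpha <- (1 - conf) / 2
  pid_levels <- sort(unique(as.character(d$participant_id)))
  P <- length(pid_levels)

  per_T <- lapply(investments, function(T) {
    qual <- d[d$waited_s >= T & d$delay_r > T, , drop = FALSE]
    if (!is.null(remaining_max))
      qual <- qual[qual$delay_r - T <= remaining_max, , drop = FALSE]
    if (nrow(qual) == 0) return(NULL)
    qual$remaining <- qual$delay_r - T
    pid <- factor(qual$participant_id, levels = pid_levels)
    rem <- factor(qual$remaining, levels = sort(unique(qual$remaining)))
    n_mat <- unclass(table(pid, rem))
    c_mat <- unclass(table(pid[qual$completed], rem[qual$completed]))
    list(n = n_mat, c = c_mat, r = as.numeric(colnames(n_mat)),
         n_trials = nrow(qual))
  })
  names(per_T) <- as.character(investments)

  point_slope <- function(m) {
    if (is.null(m)) return(list(slope = NA_real_, curve = NULL))
    n_r <- colSums(m$n)
    c_r <- colSums(m$c)
    if (aggregate == "pooled") {
      p_r <- ifelse(n_r > 0, c_r / n_r, NA_real_)
      slope <- .wls_slope(m$r, p_r, n_r)
    } else {
      p_mat <- m$c / m$n  # NaN where a participant lacks the bin
      p_r <- colMeans(p_mat, na.rm = TRUE)
      slope <- .wls_slope(m$r, p_r, colSums(m$n > 0))
    }
    list(slope = slope,
         curve = tibble::tibble(remaining = m$r, n = as.integer(n_r),
                                n_complete = as.integer(c_r), p_complete = p_r))
  }

  pts <- lapply(per_T, point_slope)
  curves <- dplyr::bind_rows(lapply(seq_along(investments), function(i) {
    cv <- pts[[i]]$curve
    if (is.null(cv)) return(NULL)
    cv$invested <- investments[i]
    cv[, c("invested", "remaining", "n", "n_complete", "p_complete")]
  }))

  # Joint bootstrap: one set of participant resamples shared by every
  # investment level, so slope differences inherit the trial overlap.
  bs <- NULL
  if (bootstrap > 0 && P > 0) {
    bs <- .with_seed(seed, {
      draws <- matrix(sample.int(P, P * bootstrap, replace = TRUE), nrow = P)
      W <- apply(draws, 2, tabulate, nbins = P)
      if (is.null(dim(W))) W <- matrix(W, nrow = P)
      vapply(per_T, function(m) {
        if (is.null(m)) return(rep(NA_real_, bootstrap))
        n_b <- crossprod(m$n, W)
        c_b <- crossprod(m$c, W)
        vapply(seq_len(ncol(n_b)), function(b) {
          nb <- n_b[, b]
          ok <- nb > 0
          .wls_slope(m$r[ok], c_b[ok, b] / nb[ok], nb[ok])
        }, numeric(1))
      }, numeric(bootstrap))
    })
  }
  ci_of <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(c(NA_real_, NA_real_))
    stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
  }
  slopes <- dplyr::bind_rows(lapply(seq_along(investments), function(i) {
    m <- per_T[[i]]
    if (is.null(m))
      rlang::inform(sprintf("no qualifying trials at investment %g s",
                            investments[i]))
    ci <- if (!is.null(bs)) ci_of(bs[, i]) else c(NA_real_, NA_real_)
    tibble::tibble(invested = investments[i], slope = pts[[i]]$slope,
                   ci_lo = ci[1], ci_hi = ci[2],
                   n_trials = if (is.null(m)) 0L else m$n_trials)
  }))
  slope_diffs <- NULL
  if (length(investments) > 1) {
    pairs <- utils::combn(seq_along(investments), 2)
    slope_diffs <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      ci <- if (!is.null(bs)) ci_of(bs[, i1] - bs[, i2]) else c(NA_real_, NA_real_)
      tibble::tibble(invested_1 = investments[i1],
                     invested_2 = investments[i2],
                     diff = pts[[i1]]$slope - pts[[i2]]$slope,
                     ci_lo = ci[1], ci_hi = ci[2])
    }))
  }
  structure(list(curves = curves, slopes = slopes, slope_diffs = slope_diffs,
                 aggregate = aggregate, conf = conf),
            class = "completion_curves")
}

#' @export
print.completion_curves <- function(x, ...) {
  cat("<completion_curves>\n")
  print(x$slopes)
  invisible(x)
}

#' Entry bias as a sunk cost: logistic choice model
#'
#' Fits a logistic regression of the stay/skip choice on deviation-coded
#' offer value type (-0.5 = below threshold / good, +0.5 = above threshold /
#' poor), continuous entry bias (signed fraction of hallway width, -0.5 to
#' +0.5, negative toward the reward side), their interaction, optional
#' gender terms, and per-participant fixed intercepts. A negative entry-bias
#' coefficient means rightward (exit-side) entries reduce acceptance — entry
#' position acting as an irrecoverable effort investment. Boundary
#' (value = 0) trials are excluded from the deviation coding.
#'
#' Complete separation (a participant with all-stay or all-skip choices)
#' makes that participant's intercept diverge; such intercepts are clamped
#' with a weak ridge penalty (two pseudo-observations of half a success at
#' zero bias), with a warning.
#'
#' @param data Data frame with `participant_id`, `entry_bias` (fraction) or
#'   `entry_position`, `value_type`, and `choice` (0/1) or `decision`.
#' @param include_gender Add gender main effect and two-way interactions
#'   (requires a `gender` column with values `"male"` / `"female"`).
#' @param ridge Total pseudo-observation weight per separated participant.
#' @return An object of class `entry_bias_model` with `coefficients` (term,
#'   estimate, se, Wald CI), `participant_intercepts`, and the `glm` fit.
#' @export
fit_entry_bias_model <- function(data, include_gender = FALSE, ridge = 0.02) {
  d <- as.data.frame(data)
  if (!"choice" %in% names(d)) {
    if (!"decision" %in% names(d))
      rlang::abort("need a `choice` (0/1) or `decision` column")
    d$choice <- as.integer(d$decision == "stay")
  }
  if (!"entry_bias" %in% names(d)) {
    if (!"entry_position" %in% names(d))
      rlang::abort("need an `entry_bias` (fraction) or `entry_position` column")
    d$entry_bias <- d$entry_position
  }
  d <- d[!is.na(d$value_type) & d$value_type %in% c("good", "poor") &
           !is.na(d$entry_bias) & !is.na(d$choice), , drop = FALSE]
  if (length(unique(d$participant_id)) < 2)
    rlang::abort("entry-bias model requires at least 2 participants",
                 class = "rowforage_data_error")
  if (length(unique(d$value_type)) < 2)
    rlang::abort("both value types (good and poor) must be present",
                 class = "rowforage_data_error")
  d$value_dev <- ifelse(d$value_type == "poor", 0.5, -0.5)
  d$participant <- factor(d$participant_id)
  d$w <- 1
  form <- choice ~ 0 + participant + value_dev + entry_bias + value_dev:entry_bias
  if (include_gender) {
    d <- d[d$gender %in% c("male", "female"), , drop = FALSE]
    d$gender_dev <- ifelse(d$gender == "female", 0.5, -0.5)
    form <- choice ~ 0 + participant + value_dev + entry_bias + gender_dev +
      value_dev:entry_bias + value_dev:gender_dev + entry_bias:gender_dev
  }

  by_p <- tapply(d$choice, d$participant, mean)
  separated <- names(by_p)[by_p %in% c(0, 1)]
  if (length(separated) > 0) {
    rlang::warn(sprintf(
      "%d participant(s) with all-stay or all-skip choices; intercepts clamped via weak ridge penalty",
      length(separated)))
    pseudo <- d[match(separated, d$participant_id), , drop = FALSE]
    pseudo <- pseudo[rep(seq_len(nrow(pseudo)), each = 2), , drop = FALSE]
    pseudo$choice <- rep(c(0, 1), length(separated))
    pseudo$entry_bias <- 0
    pseudo$value_dev <- 0
    if (include_gender) pseudo$gender_dev <- pseudo$gender_dev
    pseudo$w <- ridge
    d <- rbind(d, pseudo)
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = d, weights = w))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  is_part <- grepl("^participant", names(cf))
  z <- stats::qnorm(0.975)
  est <- unname(cf[!is_part])
  ese <- unname(se[!is_part])
  coefs <- tibble::tibble(term = names(cf)[!is_part], estimate = est,
                          se = ese, ci_lo = est - z * ese,
                          ci_hi = est + z * ese)
  structure(list(coefficients = coefs,
                 participant_intercepts = stats::setNames(
                   unname(cf[is_part]),
                   sub("^participant", "", names(cf)[is_part])),
                 include_gender = include_gender,
                 n_trials = sum(d$w == 1), fit = fit),
            class = "entry_bias_model")
}

#' @importFrom stats qnorm
#' @export
print.entry_bias_model <- function(x, ...) {
  cat(sprintf("<entry_bias_model> %d trials, %d participants\n", x$n_trials,
              length(x$participant_intercepts)))
  print(x$coefficients)
  invisible(x)
}

#' Model-predicted acceptance changes at specified entry biases
#'
#' Uses a fitted [fit_entry_bias_model()] to predict, averaged over the
#' participant intercepts, how the probability of accepting a poor offer
#' changes when entry is biased toward the reward side (negative bias), and
#' how the probability of skipping a good offer changes when entry is biased
#' toward the exit side (positive bias), each relative to a center entry.
#'
#' @param model An `entry_bias_model`.
#' @param bias_points Entry biases in percent of hallway width (within
#'   \[-50, 50\]).
#' @return A tibble with one row per bias point: predicted change (in
#'   percentage points) in poor-offer acceptance and in good-offer skipping
#'   versus a center entry.
#' @export
bias_effect_summary <- function(model, bias_points = c(-25, 25)) {
  stopifnot(inherits(model, "entry_bias_model"))
  if (any(abs(bias_points) > 50))
    rlang::abort("bias points must lie within [-50, 50] percent",
                 class = "rowforage_config_error")
  cf <- model$coefficients
  get <- function(term) {
    i <- match(term, cf$term)
    if (is.na(i)) 0 else cf$estimate[i]
  }
  a <- model$participant_intercepts
  p_accept <- function(value_dev, bias_frac) {
    eta <- a + get("value_dev") * value_dev + get("entry_bias") * bias_frac +
      get("value_dev:entry_bias") * value_dev * bias_frac
    mean(stats::plogis(eta))
  }
  rows <- lapply(bias_points, function(b) {
    f <- b / 100
    tibble::tibble(
      bias_pct = b,
      poor_accept_change_pp = 100 * (p_accept(0.5, f) - p_accept(0.5, 0)),
      good_skip_change_pp = 100 * ((1 - p_accept(-0.5, f)) -
                                     (1 - p_accept(-0.5, 0))))
  })
  dplyr::bind_rows(rows)
}
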