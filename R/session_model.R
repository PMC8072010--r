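# Canonical column sets for the tabular session format.
# Units: all timestamps are integer milliseconds from session start; delays and
# waited time are seconds; positions are track units; entry_position is a
# signed fraction of hallway width in [-0.5, +0.5] (negative = toward the
# reward side). Documented in inst/extdata/SCHEMA.md.
.trial_cols <- c("trial_index", "zone_id", "category", "offered_delay",
                 "decision", "t_offer", "t_move", "t_exit", "t_delay_start",
                 "t_quit_or_complete", "waited_s", "entry_position")
.traj_cols <- c("trial_index", "t", "x", "y", "heading")
.mag_cols <- c("zone_id", "t_start", "duration_ms")
.session_cols <- c("participant_id", "task_variant", "version", "setting",
                   "gender", "age", "bmi_group", "smoker")
.decisions <- c("stay", "skip", "quit")

.coerce_trials <- function(trials) {
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  missing_required <- setdiff(c("trial_index", "zone_id", "category",
                                "offered_delay", "decision", "t_offer",
                                "t_exit"), names(trials))
  if (length(missing_required) > 0) {
    rlang::abort(paste0("schema error: missing trial column(s): ",
                        paste(missing_required, collapse = ", ")),
                 class = "rowforage_schema_error")
  }
  for (col in setdiff(.trial_cols, names(trials))) trials[[col]] <- NA
  int_cols <- c("trial_index", "zone_id", "t_offer", "t_move", "t_exit",
                "t_delay_start", "t_quit_or_complete")
  for (col in int_cols) trials[[col]] <- as.integer(round(as.numeric(trials[[col]])))
  for (col in c("offered_delay", "waited_s", "entry_position"))
    trials[[col]] <- as.numeric(trials[[col]])
  trials$category <- as.character(trials$category)
  trials$decision <- as.character(trials$decision)
  trials <- trials[order(trials$trial_index), .trial_cols, drop = FALSE]
  tibble::as_tibble(trials)
}

.coerce_traj <- function(trajectories) {
  if (is.null(trajectories) || (is.data.frame(trajectories) && nrow(trajectories) == 0)) {
    return(tibble::tibble(trial_index = integer(), t = integer(),
                          x = numeric(), y = numeric(), heading = numeric()))
  }
  trajectories <- as.data.frame(trajectories, stringsAsFactors = FALSE)
  missing_required <- setdiff(.traj_cols, names(trajectories))
  if (length(missing_required) > 0) {
    rlang::abort(paste0("schema error: missing trajectory column(s): ",
                        paste(missing_required, collapse = ", ")),
                 class = "rowforage_schema_error")
  }
  trajectories$trial_index <- as.integer(trajectories$trial_index)
  trajectories$t <- as.integer(round(as.numeric(trajectories$t)))
  for (col in c("x", "y", "heading")) trajectories[[col]] <- as.numeric(trajectories[[col]])
  trajectories <- trajectories[order(trajectories$trial_index, trajectories$t),
                               .traj_cols, drop = FALSE]
  tibble::as_tibble(trajectories)
}

.coerce_mag <- function(magazine) {
  if (is.null(magazine) || (is.data.frame(magazine) && nrow(magazine) == 0)) {
    return(tibble::tibble(zone_id = integer(), t_start = integer(),
                          duration_ms = integer()))
  }
  magazine <- as.data.frame(magazine, stringsAsFactors = FALSE)
  missing_required <- setdiff(.mag_cols, names(magazine))
  if (length(missing_required) > 0) {
    rlang::abort(paste0("schema error: missing magazine column(s): ",
                        paste(missing_required, collapse = ", ")),
                 class = "rowforage_schema_error")
  }
  magazine$zone_id <- as.integer(magazine$zone_id)
  magazine$t_start <- as.integer(round(as.numeric(magazine$t_start)))
  magazine$duration_ms <- as.integer(round(as.numeric(magazine$duration_ms)))
  tibble::as_tibble(magazine[order(magazine$t_start), .mag_cols, drop = FALSE])
}

#' Construct a foraging session
#'
#' A `row_session` bundles one participant's run of the Movie Row or Candy Row
#' task: the trial table (one row per offer), the within-offer-zone trajectory
#' samples, and (Candy Row only) the magazine beam-break log.
#'
#' Timestamps are integer milliseconds from session start; offered delays and
#' waited times are seconds. `entry_position` is the lateral position on
#' entering the offer zone as a signed fraction of hallway width in
#' \[-0.5, +0.5\], negative toward the reward side.
#'
#' @param participant_id Participant identifier (character scalar).
#' @param trials Data frame of trials; required columns are `trial_index`
#'   (0-based, contiguous), `zone_id` (0-3), `category`, `offered_delay` (s),
#'   `decision` (`"stay"`, `"skip"` or `"quit"`), `t_offer` and `t_exit` (ms).
#'   Optional: `t_move` (versions 3-4), `t_delay_start`, `t_quit_or_complete`,
#'   `waited_s`, `entry_position`.
#' @param trajectories Data frame of position samples with columns
#'   `trial_index`, `t` (ms), `x`, `y` (track units), `heading` (degrees in
#'   \[0, 360)). May be `NULL`.
#' @param magazine Data frame of infrared beam breaks with columns `zone_id`,
#'   `t_start` (ms), `duration_ms` (Candy Row). May be `NULL`.
#' @param task_variant `"movie"` or `"candy"`.
#' @param version Task version, 1-4. Versions 3-4 record `t_move` (the gate
#'   releases the avatar, so reaction time is measurable).
#' @param setting `"in_person"` or `"online"`.
#' @param covariates Named list; recognized entries are `gender`, `age`,
#'   `bmi_group` (`"<25"`, `">=25"`, `"unknown"`) and `smoker`.
#'
#' @return An object of class `row_session`.
#' @seealso [validate_session()], [read_sessions()], [write_sessions()]
#' @export
new_session <- function(participant_id, trials, trajectories = NULL,
                        magazine = NULL, task_variant = c("movie", "candy"),
                        version = 1L, setting = c("in_person", "online"),
                        covariates = list()) {
  task_variant <- match.arg(task_variant)
  setting <- match.arg(setting)
  version <- as.integer(version)
  if (!version %in% 1:4) rlang::abort("`version` must be 1, 2, 3 or 4")
  cov <- list(gender = "unknown", age = NA_real_, bmi_group = "unknown",
              smoker = "unknown")
  cov[intersect(names(covariates), names(cov))] <-
    covariates[intersect(names(covariates), names(cov))]
  structure(list(participant_id = as.character(participant_id)[1],
                 task_variant = task_variant, version = version,
                 setting = setting, covariates = cov,
                 trials = .coerce_trials(trials),
                 trajectories = .coerce_traj(trajectories),
                 magazine = .coerce_mag(magazine)),
            class = "row_session")
}

#' @export
print.row_session <- function(x, ...) {
  cat(sprintf("<row_session> %s  %s v%d (%s)\n", x$participant_id,
              x$task_variant, x$version, x$setting))
  cat(sprintf("  %d trials, %d trajectory samples, %d magazine events\n",
              nrow(x$trials), nrow(x$trajectories), nrow(x$magazine)))
  invisible(x)
}

#' List invariant violations in a session
#'
#' Checks every documented invariant of the session data model and returns one
#' row per violation. Trial-level rows carry the offending `trial_index`;
#' session-level problems (e.g. a non-contiguous trial index) have `NA`.
#'
#' @param session A `row_session`.
#' @return A tibble with columns `trial_index`, `field`, `reason`.
#' @export
session_violations <- function(session) {
  stopifnot(inherits(session, "row_session"))
  tr <- session$trials
  out <- list()
  add <- function(trial_index, field, reason) {
    out[[length(out) + 1]] <<- tibble::tibble(trial_index = as.integer(trial_index),
                                              field = field, reason = reason)
  }
  if (nrow(tr) < 1) add(NA, "trials", "session has no trials")
  if (nrow(tr) > 0 && !identical(tr$trial_index, seq_len(nrow(tr)) - 1L))
    add(NA, "trial_index", "trial_index not contiguous from 0")
  if (length(unique(tr$category)) > 4)
    add(NA, "category", "more than four distinct reward categories")

  for (i in seq_len(nrow(tr))) {
    ti <- tr$trial_index[i]
    if (!tr$zone_id[i] %in% 0:3) add(ti, "zone_id", "zone_id not in 0-3")
    if (!tr$decision[i] %in% .decisions)
      add(ti, "decision", "decision not one of stay/skip/quit")
    if (!is.finite(tr$offered_delay[i]) || tr$offered_delay[i] <= 0)
      add(ti, "offered_delay", "offered_delay must be > 0")
    if (is.na(tr$t_offer[i]) || is.na(tr$t_exit[i])) {
      add(ti, "timestamps", "t_offer and t_exit are required")
    } else {
      if (tr$t_exit[i] < tr$t_offer[i])
        add(ti, "timestamps", "t_exit < t_offer")
      if (!is.na(tr$t_move[i]) &&
          (tr$t_move[i] < tr$t_offer[i] || tr$t_move[i] > tr$t_exit[i]))
        add(ti, "timestamps", "t_move outside [t_offer, t_exit]")
    }
    if (identical(tr$decision[i], "quit")) {
      if (is.na(tr$t_delay_start[i]))
        add(ti, "t_delay_start", "quit requires t_delay_start")
      if (is.na(tr$waited_s[i]) || is.na(tr$offered_delay[i]) ||
          !isTRUE(tr$waited_s[i] < tr$offered_delay[i]))
        add(ti, "waited_s", "quit requires waited_s < offered_delay")
    }
    if (identical(tr$decision[i], "stay") && !is.na(tr$waited_s[i]) &&
        !isTRUE(abs(tr$waited_s[i] - tr$offered_delay[i]) < 1e-9))
      add(ti, "waited_s", "stay requires the full delay to be completed")
    if (!is.na(tr$entry_position[i]) && abs(tr$entry_position[i]) > 0.5 + 1e-12)
      add(ti, "entry_position", "entry_position outside [-0.5, 0.5]")
  }

  tj <- session$trajectories
  if (nrow(tj) > 0) {
    if (any(tj$heading < 0 | tj$heading >= 360, na.rm = TRUE))
      add(NA, "heading", "heading outside [0, 360)")
    sp <- split(seq_len(nrow(tj)), tj$trial_index)
    for (key in names(sp)) {
      idx <- sp[[key]]
      ti <- as.integer(key)
      t_v <- tj$t[idx]
      if (any(diff(t_v) <= 0))
        add(ti, "trajectory", "trajectory timestamps not strictly increasing")
      row <- match(ti, tr$trial_index)
      if (!is.na(row)) {
        if (any(t_v < tr$t_offer[row]) || any(t_v > tr$t_exit[row]))
          add(ti, "trajectory", "trajectory sample outside [t_offer, t_exit]")
      } else {
        add(ti, "trajectory", "trajectory references unknown trial")
      }
    }
  }
  if (nrow(session$magazine) > 0 && any(session$magazine$duration_ms <= 0))
    add(NA, "magazine", "beam-break duration must be > 0")

  if (length(out) == 0) {
    tibble::tibble(trial_index = integer(), field = character(),
                   reason = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Validate a session, erroring on any invariant violation
#'
#' @param session A `row_session`.
#' @return The session, invisibly, if valid. Otherwise a validation error
#'   naming each offending trial and reason.
#' @export
validate_session <- function(session) {
  v <- session_violations(session)
  if (nrow(v) > 0) {
    lines <- sprintf("%s: %s",
                     ifelse(is.na(v$trial_index), "session",
                            paste0("trial ", v$trial_index)), v$reason)
    rlang::abort(paste0("invalid session '", session$participant_id, "':\n  ",
                        paste(lines, collapse = "\n  ")),
                 class = "rowforage_validation_error")
  }
  invisible(session)
}

# Drop trajectory samples after the first offer-zone exit (re-entry behavior
# is excluded from all offer-zone measures); the log writer already truncates,
# this is defense in depth at read time.
.truncate_reentry <- function(session) {
  tj <- session$trajectories
  if (nrow(tj) == 0) return(session)
  t_exit <- session$trials$t_exit[match(tj$trial_index, session$trials$trial_index)]
  keep <- is.na(t_exit) | tj$t <= t_exit
  session$trajectories <- tj[keep, , drop = FALSE]
  session
}

.session_row <- function(s) {
  tibble::tibble(participant_id = s$participant_id,
                 task_variant = s$task_variant, version = s$version,
                 setting = s$setting,
                 gender = as.character(s$covariates$gender),
                 age = as.numeric(s$covariates$age),
                 bmi_group = as.character(s$covariates$bmi_group),
                 smoker = as.character(s$covariates$smoker))
}

#' Write sessions to disk
#'
#' `csv_bundle` writes four CSV files into the directory `path`:
#' `sessions.csv` (session-level fields), `trials.csv`, `trajectories.csv` and
#' `magazine.csv`, all keyed by `participant_id`. `jsonl` writes one JSON
#' object per session per line. Both formats round-trip losslessly through
#' [read_sessions()]. An empty session list produces header-only files.
#'
#' @param sessions A `row_session` or list of them.
#' @param path Output directory (`csv_bundle`) or file path (`jsonl`).
#' @param format `"csv_bundle"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path, format = c("csv_bundle", "jsonl")) {
  format <- match.arg(format)
  if (inherits(sessions, "row_session")) sessions <- list(sessions)
  stopifnot(all(vapply(sessions, inherits, logical(1), "row_session")))
  ids <- vapply(sessions, `[[`, character(1), "participant_id")
  if (anyDuplicated(ids))
    rlang::abort("duplicate participant_id in session list")

  if (format == "csv_bundle") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    key <- function(df, id) {
      if (nrow(df) == 0) df$participant_id <- character(0)
      else df$participant_id <- id
      df[, c("participant_id", setdiff(names(df), "participant_id")), drop = FALSE]
    }
    sess <- dplyr::bind_rows(lapply(sessions, .session_row))
    if (length(sessions) == 0)
      sess <- stats::setNames(
        as.data.frame(matrix(nrow = 0, ncol = length(.session_cols))), .session_cols)
    trials <- dplyr::bind_rows(lapply(sessions, function(s) key(s$trials, s$participant_id)))
    traj <- dplyr::bind_rows(lapply(sessions, function(s) key(s$trajectories, s$participant_id)))
    mag <- dplyr::bind_rows(lapply(sessions, function(s) key(s$magazine, s$participant_id)))
    if (length(sessions) == 0) {
      trials <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 1 + length(.trial_cols))),
                                c("participant_id", .trial_cols))
      traj <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 1 + length(.traj_cols))),
                              c("participant_id", .traj_cols))
      mag <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = 1 + length(.mag_cols))),
                             c("participant_id", .mag_cols))
    }
    utils::write.csv(sess, file.path(path, "sessions.csv"), row.names = FALSE)
    utils::write.csv(trials, file.path(path, "trials.csv"), row.names = FALSE)
    utils::write.csv(traj, file.path(path, "trajectories.csv"), row.names = FALSE)
    utils::write.csv(mag, file.path(path, "magazine.csv"), row.names = FALSE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con), add = TRUE)
    for (s in sessions) {
      obj <- list(participant_id = s$participant_id,
                  task_variant = s$task_variant, version = s$version,
                  setting = s$setting, covariates = s$covariates,
                  trials = s$trials, trajectories = s$trajectories,
                  magazine = s$magazine)
      writeLines(jsonlite::toJSON(obj, dataframe = "columns", na = "null",
                                  auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Read sessions from disk
#'
#' Reads and validates sessions written by [write_sessions()] (or any files
#' conforming to the documented schema). Trajectory samples recorded after the
#' first offer-zone exit are dropped (re-entry behavior is excluded from the
#' offer-zone measures).
#'
#' With `strict = TRUE` (default) any invariant violation raises a validation
#' error naming the offending trials. With `strict = FALSE` trial-level
#' violators are rejected (the trial and its trajectory are dropped) and a
#' report of row numbers and reasons is attached as the `"validation_report"`
#' attribute; session-level violations still error.
#'
#' @param path Directory (`csv_bundle`) or file (`jsonl`).
#' @param format `"csv_bundle"` or `"jsonl"`.
#' @param strict Error on any violation (default) or drop offending trials.
#' @return A list of `row_session` objects.
#' @export
read_sessions <- function(path, format = c("csv_bundle", "jsonl"),
                          strict = TRUE) {
  format <- match.arg(format)
  sessions <- if (format == "csv_bundle") .read_csv_bundle(path)
              else .read_jsonl(path)
  report <- list()
  sessions <- lapply(sessions, function(s) {
    s <- .truncate_reentry(s)
    v <- session_violations(s)
    if (nrow(v) == 0) return(s)
    if (strict) {
      lines <- sprintf("%s: %s",
                       ifelse(is.na(v$trial_index), "session",
                              paste0("trial ", v$trial_index)), v$reason)
      rlang::abort(paste0("invalid session '", s$participant_id, "':\n  ",
                          paste(lines, collapse = "\n  ")),
                   class = "rowforage_validation_error")
    }
    if (any(is.na(v$trial_index))) {
      bad <- v[is.na(v$trial_index), ]
      rlang::abort(paste0("session-level violation in '", s$participant_id,
                          "': ", paste(bad$reason, collapse = "; ")),
                   class = "rowforage_validation_error")
    }
    drop <- unique(v$trial_index)
    report[[s$participant_id]] <<- dplyr::mutate(v, participant_id = s$participant_id)
    s$trials <- s$trials[!s$trials$trial_index %in% drop, , drop = FALSE]
    s$trajectories <- s$trajectories[!s$trajectories$trial_index %in% drop, , drop = FALSE]
    s
  })
  if (length(report) > 0)
    attr(sessions, "validation_report") <- dplyr::bind_rows(report)
  sessions
}

.read_csv_bundle <- function(path) {
  f <- function(name) file.path(path, name)
  for (name in c("sessions.csv", "trials.csv")) {
    if (!file.exists(f(name)))
      rlang::abort(paste0("schema error: missing file ", name),
                   class = "rowforage_schema_error")
  }
  sess <- utils::read.csv(f("sessions.csv"), stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("participant_id", "task_variant", "version", "setting"),
                          names(sess))
  if (length(missing_cols) > 0)
    rlang::abort(paste0("schema error: sessions.csv missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "rowforage_schema_error")
  trials <- utils::read.csv(f("trials.csv"), stringsAsFactors = FALSE)
  if (!"participant_id" %in% names(trials))
    rlang::abort("schema error: trials.csv missing column(s): participant_id",
                 class = "rowforage_schema_error")
  traj <- if (file.exists(f("trajectories.csv")))
    utils::read.csv(f("trajectories.csv"), stringsAsFactors = FALSE) else NULL
  mag <- if (file.exists(f("magazine.csv")))
    utils::read.csv(f("magazine.csv"), stringsAsFactors = FALSE) else NULL
  lapply(seq_len(nrow(sess)), function(i) {
    id <- as.character(sess$participant_id[i])
    cov <- list(gender = if ("gender" %in% names(sess)) sess$gender[i] else "unknown",
                age = if ("age" %in% names(sess)) sess$age[i] else NA_real_,
                bmi_group = if ("bmi_group" %in% names(sess)) sess$bmi_group[i] else "unknown",
                smoker = if ("smoker" %in% names(sess)) sess$smoker[i] else "unknown")
    new_session(participant_id = id,
                trials = trials[trials$participant_id == id, , drop = FALSE],
                trajectories = if (!is.null(traj) && nrow(traj) > 0)
                  traj[traj$participant_id == id, , drop = FALSE] else NULL,
                magazine = if (!is.null(mag) && nrow(mag) > 0)
                  mag[mag$participant_id == id, , drop = FALSE] else NULL,
                task_variant = sess$task_variant[i],
                version = sess$version[i], setting = sess$setting[i],
                covariates = cov)
  })
}

.read_jsonl <- function(path) {
  if (!file.exists(path))
    rlang::abort(paste0("schema error: missing file ", path),
                 class = "rowforage_schema_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    as_df <- function(x, cols) {
      if (is.null(x) || length(x) == 0) return(NULL)
      as.data.frame(x[cols[cols %in% names(x)]], stringsAsFactors = FALSE)
    }
    new_session(participant_id = obj$participant_id,
                trials = as.data.frame(obj$trials, stringsAsFactors = FALSE),
                trajectories = as_df(obj$trajectories, .traj_cols),
                magazine = as_df(obj$magazine, .mag_cols),
                task_variant = obj$task_variant, version = obj$version,
                setting = obj$setting, covariates = obj$covariates)
  })
}

#' Score reward retrievals from magazine beam breaks
#'
#' Breaks of the magazine infrared beam lasting between 50 ms and 10 s
#' (inclusive on both ends) are scored as retrievals; later breaks are
#' discarded because leftover food can obstruct the sensor, so scoring is
#' restricted to the first 20 minutes by default.
#'
#' @param events Data frame of beam breaks (`zone_id`, `t_start` ms,
#'   `duration_ms`); sorted by `t_start` internally, so input order is
#'   irrelevant.
#' @param window_end Only breaks starting strictly before this time (ms) are
#'   scored. Default 20 minutes.
#' @param min_ms,max_ms Inclusive duration bounds for a retrieval.
#' @return A tibble of retained retrievals (`zone_id`, `t_start`,
#'   `duration_ms`), time-sorted.
#' @export
score_magazine_retrievals <- function(events, window_end = 20 * 60 * 1000,
                                      min_ms = 50, max_ms = 10000) {
  events <- .coerce_mag(events)
  if (any(events$duration_ms <= 0))
    rlang::abort("beam-break duration must be positive",
                 class = "rowforage_validation_error")
  keep <- events$duration_ms >= min_ms & events$duration_ms <= max_ms &
    events$t_start < window_end
  events[keep, , drop = FALSE]
}
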