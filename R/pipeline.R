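#' Pipeline run configuration
#'
#' Bundles every knob of a full analysis run. All stochastic steps derive
#' their streams from `seed`, and the configuration hash is stamped into
#' every output header, so identical config + seed gives byte-identical
#' numeric tables.
#'
#' @param out_dir Output directory (required by [run_pipeline()]).
#' @param input Optional path to an existing session bundle; `NULL` simulates
#'   a cohort instead.
#' @param input_format Format of `input` (`"csv_bundle"` or `"jsonl"`).
#' @param n_participants Cohort size when simulating.
#' @param seed Master seed.
#' @param task_variant,n_circuits,include_trajectories Simulation settings
#'   (see [generate_cohort()] and [task_config()]).
#' @param bin_width,jitter_deg,move_eps Metric parameters.
#' @param investments,bootstrap Completion-curve settings.
#' @param bias_points Entry-bias prediction points (percent).
#' @param item_bank Discounting item bank name or path.
#' @param simulate_surveys Score simulated survey responses (one responder
#'   per participant with log-normal k) when no survey data are supplied.
#' @return A `row_config` list.
#' @export
row_config <- function(out_dir = NULL, input = NULL,
                       input_format = "csv_bundle", n_participants = 50,
                       seed = 1L, task_variant = "movie", n_circuits = NULL,
                       include_trajectories = TRUE, bin_width = 2,
                       jitter_deg = 1, move_eps = 1e-6,
                       investments = c(0, 5, 10), bootstrap = 2000,
                       bias_points = c(-25, 25), item_bank = "mcq21",
                       simulate_surveys = TRUE) {
  structure(list(out_dir = out_dir, input = input,
                 input_format = input_format,
                 n_participants = n_participants, seed = as.integer(seed),
                 task_variant = task_variant, n_circuits = n_circuits,
                 include_trajectories = include_trajectories,
                 bin_width = bin_width, jitter_deg = jitter_deg,
                 move_eps = move_eps, investments = investments,
                 bootstrap = bootstrap, bias_points = bias_points,
                 item_bank = item_bank, simulate_surveys = simulate_surveys),
            class = "row_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the [row_config()] arguments.
#' @return A `row_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    rlang::abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  do.call(row_config, vals[intersect(names(vals), names(formals(row_config)))])
}

# TSV writer used for every numeric output table: header comment records
# package version and config hash for provenance.
.write_tsv <- function(df, path, config_hash) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# rowforage %s config_hash=%s",
                     as.character(utils::packageVersion("rowforage")),
                     config_hash), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline output TSV (skipping the provenance header)
#'
#' @param path TSV written by [run_pipeline()].
#' @return A tibble.
#' @export
read_output_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#",
                                      stringsAsFactors = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> thresholds -> offer-zone metrics ->
#' value tuning -> context labels and contrasts -> sunk-cost analyses ->
#' discounting into one reproducible run. Every stage's table is written as
#' TSV under `config$out_dir` with a provenance header; a structured run log
#' (stage, counts in/out, exclusion tallies) goes to `run_log.txt` and, when
#' `quiet = FALSE`, to the console. A stage failure aborts with the stage
#' name; tables already written are preserved.
#'
#' @param config A [row_config()].
#' @param quiet Suppress console logging.
#' @return Invisibly, a list with all stage results and the log path.
#' @export
run_pipeline <- function(config = row_config(), quiet = FALSE) {
  stopifnot(inherits(config, "row_config"))
  if (is.null(config$out_dir))
    rlang::abort("config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(unclass(config))
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  log_line <- function(stage, ...) {
    msg <- sprintf("stage=%s %s", stage, paste(sprintf(...), collapse = " "))
    writeLines(msg, log_con)
    if (!quiet) rlang::inform(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)), parent = e)
    })
  }
  out <- list(config = config, log_path = log_path)

  sessions <- stage("input", {
    if (!is.null(config$input)) {
      if (!file.exists(config$input))
        rlang::abort(paste0("input not found: ", config$input))
      s <- read_sessions(config$input, format = config$input_format)
      log_line("input", "read=%d path=%s", length(s), config$input)
      s
    } else {
      s <- generate_cohort(config$n_participants,
                           task = task_config(n_circuits = config$n_circuits),
                           task_variant = config$task_variant,
                           seed = .child_seed(config$seed, 1),
                           include_trajectories = config$include_trajectories)
      log_line("simulate", "n_participants=%d seed=%d",
               config$n_participants, config$seed)
      s
    }
  })
  out$sessions <- sessions

  thr <- stage("thresholds", {
    fits <- lapply(sessions, fit_thresholds)
    summary <- dplyr::bind_rows(lapply(fits, `[[`, "summary"))
    trials <- dplyr::bind_rows(lapply(fits, `[[`, "trials"))
    .write_tsv(summary, file.path(config$out_dir, "thresholds_summary.tsv"), hash)
    .write_tsv(trials, file.path(config$out_dir, "thresholds_trials.tsv"), hash)
    log_line("thresholds", "participants=%d normal=%d", length(fits),
             sum(summary$pattern == "normal"))
    list(summary = summary, trials = trials)
  })
  out$thresholds <- thr

  metrics <- stage("metrics", {
    per <- lapply(sessions, function(s)
      suppressWarnings(offer_zone_metrics(s, jitter_deg = config$jitter_deg,
                                          move_eps = config$move_eps)))
    tallies <- lapply(per, attr, "exclusion_tally")
    m <- dplyr::bind_rows(per)
    m <- dplyr::left_join(
      m, thr$trials[, c("participant_id", "trial_index", "value",
                        "value_type", "abs_value")],
      by = c("participant_id", "trial_index"))
    .write_tsv(m, file.path(config$out_dir, "metrics.tsv"), hash)
    log_line("metrics",
             "trials=%d excluded_latency=%d excluded_rotation_only=%d excluded_reaction=%d",
             nrow(m), sum(vapply(tallies, `[[`, numeric(1), "latency")),
             sum(vapply(tallies, `[[`, numeric(1), "rotation_only")),
             sum(vapply(tallies, `[[`, numeric(1), "reaction")))
    attr(m, "exclusion_tally") <- list(
      latency = sum(vapply(tallies, `[[`, numeric(1), "latency")),
      rotation_only = sum(vapply(tallies, `[[`, numeric(1), "rotation_only")),
      reaction = sum(vapply(tallies, `[[`, numeric(1), "reaction")))
    m
  })
  out$metrics <- metrics

  tuning <- stage("value_tuning", {
    tun <- list()
    for (met in c("z_latency", "z_rotation")) {
      if (all(is.na(metrics[[met]]))) next
      tun[[met]] <- tryCatch(
        value_tuning(metrics, metric = met, bin_width = config$bin_width),
        error = function(e) NULL)
    }
    rows <- dplyr::bind_rows(lapply(names(tun), function(met)
      dplyr::mutate(tun[[met]]$summary, metric = met)))
    if (nrow(rows) > 0)
      .write_tsv(rows, file.path(config$out_dir, "value_tuning.tsv"), hash)
    log_line("value_tuning", "metrics=%s", paste(names(tun), collapse = ","))
    tun
  })
  out$value_tuning <- tuning

  context <- stage("context", {
    labelled <- dplyr::bind_rows(lapply(sessions, function(s) {
      tr <- dplyr::left_join(
        s$trials,
        thr$trials[thr$trials$participant_id == s$participant_id,
                   c("trial_index", "value", "value_type")],
        by = "trial_index")
      lab <- label_context(tr)
      lab$participant_id <- s$participant_id
      lab
    }))
    ctx <- dplyr::left_join(metrics, labelled,
                            by = c("participant_id", "trial_index"))
    .write_tsv(labelled, file.path(config$out_dir, "context_labels.tsv"), hash)
    contrasts <- list()
    for (ctrl in c("control1", "control2")) {
      contrasts[[ctrl]] <- tryCatch(
        compare_contexts(ctx, cells = c("regret", ctrl),
                         metric = "z_latency", label_col = "regret_class"),
        error = function(e) NULL)
    }
    rows <- dplyr::bind_rows(lapply(contrasts[!vapply(contrasts, is.null, logical(1))],
                                    function(cc)
      tibble::tibble(contrast = paste(cc$cells, collapse = "_vs_"),
                     mean_1 = cc$means[1], mean_2 = cc$means[2],
                     p_value = cc$p_value, n = cc$n_participants)))
    if (nrow(rows) > 0)
      .write_tsv(rows, file.path(config$out_dir, "context_contrasts.tsv"), hash)
    log_line("context", "labelled=%d regret=%d", nrow(labelled),
             sum(labelled$regret_class == "regret"))
    list(labels = labelled, contrasts = contrasts)
  })
  out$context <- context

  sunk <- stage("sunk_cost", {
    trials <- dplyr::bind_rows(lapply(sessions, function(s)
      dplyr::mutate(s$trials, participant_id = s$participant_id)))
    curves <- completion_curves(trials, investments = config$investments,
                                bootstrap = config$bootstrap,
                                seed = .child_seed(config$seed, 2))
    .write_tsv(curves$curves, file.path(config$out_dir, "completion_curves.tsv"), hash)
    .write_tsv(curves$slopes, file.path(config$out_dir, "completion_slopes.tsv"), hash)
    model_data <- dplyr::left_join(
      trials,
      thr$trials[, c("participant_id", "trial_index", "value_type")],
      by = c("participant_id", "trial_index"))
    model <- tryCatch(
      suppressWarnings(fit_entry_bias_model(
        dplyr::mutate(model_data, entry_bias = .data$entry_position))),
      error = function(e) NULL)
    if (!is.null(model)) {
      .write_tsv(model$coefficients,
                 file.path(config$out_dir, "entry_bias_model.tsv"), hash)
      .write_tsv(bias_effect_summary(model, config$bias_points),
                 file.path(config$out_dir, "entry_bias_effects.tsv"), hash)
    }
    quit_rate <- mean(trials$decision[trials$decision != "skip"] == "quit")
    log_line("sunk_cost", "started=%d quit_pct=%.3f",
             sum(trials$decision != "skip"), 100 * quit_rate)
    list(curves = curves, model = model)
  })
  out$sunk_cost <- sunk

  disc <- stage("discounting", {
    if (!config$simulate_surveys) return(NULL)
    items <- load_item_bank(config$item_bank)
    res <- .with_seed(.child_seed(config$seed, 3), {
      lapply(seq_along(sessions), function(i) {
        k_true <- 10^stats::rnorm(1, -2.3, 0.9)
        resp <- generate_survey_responses(k_true, items, noise = 0.05)
        sc <- score_survey(resp, items)
        tibble::tibble(participant_id = sessions[[i]]$participant_id,
                       k_true = k_true, k = sc$k_overall,
                       log10_k = sc$log10_k, consistency = sc$consistency)
      })
    })
    res <- dplyr::bind_rows(res)
    .write_tsv(res, file.path(config$out_dir, "discounting.tsv"), hash)
    log_line("discounting", "scored=%d mean_log10_k=%.3f", nrow(res),
             mean(res$log10_k))
    res
  })
  out$discounting <- disc

  log_line("done", "out_dir=%s", config$out_dir)
  invisible(out)
}

#' Write the small bundled fixtures used by the test-suite
#'
#' Deterministically regenerates (1) the hand-constructed context-labeling
#' fixture covering every (previous decision x previous value x current
#' value) combination with its answer key, (2) a tiny simulated cohort as a
#' csv bundle, and (3) one noiseless survey-response fixture.
#'
#' @param dir Output directory.
#' @param seed Seed for the simulated cohort.
#' @return Character vector of paths written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- context_fixture()
  p1 <- file.path(dir, "context_fixture.csv")
  utils::write.csv(fx, p1, row.names = FALSE)
  cohort <- generate_cohort(2, task = task_config(n_circuits = 5),
                            seed = seed)
  p2 <- file.path(dir, "mini_cohort")
  write_sessions(cohort, p2, format = "csv_bundle")
  items <- load_item_bank("mcq21")
  resp <- generate_survey_responses(0.01, items)
  p3 <- file.path(dir, "survey_fixture.csv")
  utils::write.csv(data.frame(item = seq_len(nrow(items)), response = resp),
                   p3, row.names = FALSE)
  c(p1, file.path(p2, c("sessions.csv", "trials.csv", "trajectories.csv",
                        "magazine.csv")), p3)
}

#' Hand-constructed context-labeling fixture with answer key
#'
#' Nine trials whose eight consecutive transitions cover every (previous
#' decision x previous value x current value) combination once (an Eulerian
#' path over the four decision-by-value states). Good offers are 5 s against
#' a 10 s threshold (value +5), poor offers 15 s (value -5). The
#' `expected_*` columns are the hand-derived labels.
#'
#' @return A tibble with trial fields, `value_type`, and expected labels.
#' @export
context_fixture <- function() {
  tibble::tibble(
    trial_index = 0:8,
    decision = c("skip", "stay", "skip", "stay", "stay", "skip", "stay",
                 "skip", "stay"),
    offered_delay = c(5, 15, 15, 15, 5, 15, 5, 5, 5),
    loo_threshold = 10,
    value = 10 - c(5, 15, 15, 15, 5, 15, 5, 5, 5),
    value_type = c("good", "poor", "poor", "poor", "good", "poor", "good",
                   "good", "good"),
    expected_regret = c("none", "regret", "none", "control2", "none",
                        "control1", "none", "none", "none"),
    expected_sequence = c("undefined", "skip_stay", "stay_skip", "skip_stay",
                          "stay_stay", "stay_skip", "skip_stay", "stay_skip",
                          "skip_stay"))
}
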