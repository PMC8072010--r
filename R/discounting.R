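#' Load a delay-discounting item bank
#'
#' An item bank lists forced choices between a smaller immediate reward and a
#' larger delayed one; each item implies an indifference discounting rate
#' `implied_k = (delayed/immediate - 1) / delay` — the hyperbolic rate at
#' which both options have equal present value `A / (1 + k D)`.
#'
#' Two banks ship with the package as editable CSV config files:
#' `"mcq21"` (21 monetary items, 3 magnitude bins) and `"fcq27"` (27 food
#' items, amounts in bites). Both are synthetic stand-ins constructed on a
#' log-spaced implied-k ladder spanning the usual Kirby-style range; the
#' original instruments' exact amounts belong to their cited sources, so the
#' shipped files are labelled synthetic and are meant to be replaced with the
#' instrument actually administered.
#'
#' @param bank `"mcq21"`, `"fcq27"`, or a path to a CSV with columns
#'   `immediate_amount`, `delayed_amount`, `delay_days`, `magnitude_bin`.
#' @return A tibble of items with an `implied_k` column.
#' @export
load_item_bank <- function(bank = "mcq21") {
  path <- switch(bank,
                 mcq21 = system.file("extdata", "mcq21_items_synthetic.csv",
                                     package = "rowforage"),
                 fcq27 = system.file("extdata", "fcq27_items_synthetic.csv",
                                     package = "rowforage"),
                 bank)
  if (!file.exists(path))
    rlang::abort(paste0("item bank not found: ", path),
                 class = "rowforage_schema_error")
  items <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  required <- c("immediate_amount", "delayed_amount", "delay_days",
                "magnitude_bin")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0)
    rlang::abort(paste0("item bank missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "rowforage_schema_error")
  bad <- !(items$delayed_amount > items$immediate_amount &
             items$immediate_amount > 0 & items$delay_days > 0)
  if (any(bad))
    rlang::abort("item bank violates delayed > immediate > 0, delay > 0",
                 class = "rowforage_validation_error")
  items$implied_k <- (items$delayed_amount / items$immediate_amount - 1) /
    items$delay_days
  items
}

# Candidate rates: geometric midpoints of the sorted unique implied ks, plus
# outer bounds one geometric half-step beyond the extremes, so extreme
# responders land just outside the instrument's range.
.k_candidates <- function(ks) {
  u <- sort(unique(ks))
  if (length(u) == 1) return(u * c(0.5, 2))
  mids <- sqrt(u[-length(u)] * u[-1])
  lo <- u[1] / sqrt(u[2] / u[1])
  hi <- u[length(u)] * sqrt(u[length(u)] / u[length(u) - 1])
  c(lo, mids, hi)
}

.score_k <- function(responses, implied_k) {
  cand <- .k_candidates(implied_k)
  cons <- vapply(cand, function(k) mean((implied_k > k) == (responses == 1L)),
                 numeric(1))
  best <- abs(cons - max(cons)) < 1e-12
  list(k = exp(mean(log(cand[best]))), consistency = max(cons))
}

#' Score a delay-discounting questionnaire
#'
#' Consistency-based (Kirby-style) scoring: for each candidate rate k (the
#' geometric midpoints of the items' implied-k ladder plus outer bounds), the
#' consistency is the fraction of responses matching the prediction "choose
#' the delayed option iff the item's implied k exceeds k"; the assigned k is
#' the geometric mean of all consistency-maximizing candidates. Per-magnitude
#' bins are scored the same way within bin. An all-immediate responder lands
#' at the upper outer bound with consistency 1; an all-delayed responder at
#' the lower.
#'
#' @param responses Integer vector (1 = chose delayed, 0 = chose immediate),
#'   one per item; `NA`s drop the item with a warning, and more than 30%
#'   missing refuses to score.
#' @param items Item bank from [load_item_bank()].
#' @return An object of class `discounting_result`: `k_overall`, `log10_k`,
#'   `consistency`, and `per_bin` (tibble with per-magnitude-bin k).
#' @export
score_survey <- function(responses, items) {
  if (length(responses) != nrow(items))
    rlang::abort("response vector length must equal the item count",
                 class = "rowforage_data_error")
  miss <- is.na(responses)
  if (mean(miss) > 0.3)
    rlang::abort("more than 30% of responses missing; refusing to score",
                 class = "rowforage_data_error")
  if (any(miss)) {
    rlang::warn(sprintf("%d missing response(s); items dropped", sum(miss)))
    items <- items[!miss, , drop = FALSE]
    responses <- responses[!miss]
  }
  if (!"implied_k" %in% names(items))
    items$implied_k <- (items$delayed_amount / items$immediate_amount - 1) /
      items$delay_days
  overall <- .score_k(responses, items$implied_k)
  bins <- unique(items$magnitude_bin)
  per_bin <- dplyr::bind_rows(lapply(bins, function(b) {
    i <- items$magnitude_bin == b
    s <- .score_k(responses[i], items$implied_k[i])
    tibble::tibble(magnitude_bin = b, k = s$k, log10_k = log10(s$k),
                   consistency = s$consistency, n_items = sum(i))
  }))
  structure(list(k_overall = overall$k, log10_k = log10(overall$k),
                 consistency = overall$consistency, per_bin = per_bin,
                 n_items = nrow(items)),
            class = "discounting_result")
}

#' @export
print.discounting_result <- function(x, ...) {
  cat(sprintf("<discounting_result> k = %.5g (log10 k = %.3f), consistency %.2f, %d items\n",
              x$k_overall, x$log10_k, x$consistency, x$n_items))
  print(x$per_bin)
  invisible(x)
}

#' Magnitude effect: per-bin log10 k contrasts
#'
#' Hyperbolic discounting typically weakens with reward magnitude (smaller k
#' for larger rewards); this returns pairwise differences of per-bin
#' log10 k. Positive small-minus-large contrasts indicate the usual
#' magnitude effect.
#'
#' @param result A [score_survey()] result with at least 2 scored bins.
#' @return A tibble with `contrast` and `d_log10_k`.
#' @export
magnitude_effect <- function(result) {
  stopifnot(inherits(result, "discounting_result"))
  pb <- result$per_bin
  if (nrow(pb) < 2)
    rlang::abort("magnitude effect requires at least 2 scored bins",
                 class = "rowforage_data_error")
  pairs <- utils::combn(nrow(pb), 2)
  tibble::tibble(
    contrast = paste(pb$magnitude_bin[pairs[1, ]], "-",
                     pb$magnitude_bin[pairs[2, ]]),
    d_log10_k = pb$log10_k[pairs[1, ]] - pb$log10_k[pairs[2, ]])
}
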