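#' Absolute diagnostic error of a risk estimate
#'
#' The error of an estimate is its absolute distance, in percentage points,
#' from the vignette's correct risk value.
#'
#' @param estimate,truth Numeric vectors in `[0, 100]` (recycled).
#' @return `abs(estimate - truth)`, in `[0, 100]`.
#' @export
absolute_error <- function(estimate, truth) {
  if (any(!is.finite(estimate) | estimate < 0 | estimate > 100) ||
      any(!is.finite(truth) | truth < 0 | truth > 100)) {
    abort("estimates and truths must lie in [0, 100].",
          class = "netwisdom_invalid_input")
  }
  abs(estimate - truth)
}

#' Convert diagnostic error to normalized accuracy
#'
#' Accuracy is the negated error arranged on a 0-1 scale by min-max
#' normalization: `(-error - min) / (max - min)` where `(min, max)` bound
#' the negated error. With the default fixed theoretical bounds
#' `c(-100, 0)` this reduces to `1 - error / 100`, so accuracy and error
#' add to 1 (or to 100 on the percent scale) exactly. Observed per-sample
#' bounds can be supplied instead (`bounds = range(-error)`), in which case
#' the worst observation scores 0 and the best scores 1.
#'
#' @param error Absolute error(s) in percentage points.
#' @param bounds Length-2 numeric, `c(min, max)` of the negated error scale;
#'   default `c(-100, 0)` (fixed theoretical bounds).
#' @param as_percent If `TRUE`, return on the 0-100 percent scale.
#' @return Normalized accuracy in `[0, 1]` (or `[0, 100]`).
#' @export
#' @examples
#' accuracy_from_error(23.2, as_percent = TRUE) # 76.8
accuracy_from_error <- function(error, bounds = c(-100, 0), as_percent = FALSE) {
  stopifnot(length(bounds) == 2)
  if (bounds[2] <= bounds[1]) {
    abort("degenerate normalization bounds (max <= min).",
          class = "netwisdom_invalid_bounds")
  }
  neg <- -error
  if (any(neg < bounds[1] - 1e-9 | neg > bounds[2] + 1e-9, na.rm = TRUE)) {
    abort("error outside the range implied by `bounds`.",
          class = "netwisdom_invalid_input")
  }
  a <- (neg - bounds[1]) / (bounds[2] - bounds[1])
  if (as_percent) 100 * a else a
}

#' Build the per-clinician, per-round accuracy panel
#'
#' Joins responses to their vignette's truth and correct option and computes
#' error, normalized accuracy, and recommendation correctness for every
#' response. Clinicians missing any round of their trial are excluded from
#' the panel (the analysis covers completers) and recorded in the
#' `exclusions` attribute.
#'
#' @param responses Long response tibble (`trial_id`, `vignette_id`,
#'   `condition`, `clinician_id`, `round`, `estimate`, `recommendation`).
#' @param vignettes Vignette table with `vignette_id`, `truth`,
#'   `correct_option` (e.g. [default_vignettes()]).
#' @param norm `"fixed"` for the default theoretical bounds `c(-100, 0)`, or
#'   `"observed"` for per-dataset min-max bounds of the negated error.
#' @return The input tibble with columns `truth`, `error`, `accuracy`,
#'   `correct` added; excluded rows are recorded in `attr(, "exclusions")`.
#' @export
accuracy_panel <- function(responses, vignettes = default_vignettes(),
                           norm = c("fixed", "observed")) {
  norm <- match.arg(norm)
  panel <- responses |>
    inner_join(
      vignettes |> select("vignette_id", "truth", "correct_option"),
      by = "vignette_id"
    )
  n_rounds <- panel |>
    group_by(.data$trial_id) |>
    summarise(n_rounds = max(.data$round), .groups = "drop")
  complete <- panel |>
    inner_join(n_rounds, by = "trial_id") |>
    group_by(.data$trial_id, .data$clinician_id) |>
    filter(n_distinct(.data$round) == .data$n_rounds[1]) |>
    ungroup() |>
    select(-"n_rounds")
  excluded <- anti_join(panel, complete,
                        by = c("trial_id", "clinician_id", "round"))

  bounds <- if (norm == "fixed") c(-100, 0) else {
    err <- absolute_error(complete$estimate, complete$truth)
    range(-err)
  }
  out <- complete |>
    mutate(
      error = absolute_error(.data$estimate, .data$truth),
      accuracy = accuracy_from_error(.data$error, bounds = bounds),
      correct = .data$recommendation == .data$correct_option
    ) |>
    select(-"correct_option")
  attr(out, "exclusions") <- excluded |>
    distinct(.data$trial_id, .data$clinician_id)
  attr(out, "norm_bounds") <- bounds
  out
}

#' Summarise each clinician across rounds
#'
#' Collapses an accuracy panel to one row per clinician: initial and final
#' accuracy, accuracy change (percentage points), revision magnitude
#' (absolute change in the raw estimate from first to final round), and
#' initial/final recommendation correctness.
#'
#' @param panel Output of [accuracy_panel()].
#' @param from_round,to_round Rounds compared (defaults 1 and the last).
#' @return Tibble with one row per (trial, clinician).
#' @export
clinician_summary <- function(panel, from_round = 1L, to_round = NULL) {
  if (is.null(to_round)) to_round <- max(panel$round)
  missing_rounds <- setdiff(c(from_round, to_round), unique(panel$round))
  if (length(missing_rounds) > 0) {
    abort(sprintf("round %s not present in panel.", missing_rounds),
          class = "netwisdom_invalid_parameters")
  }
  first <- panel |> filter(.data$round == from_round)
  last <- panel |> filter(.data$round == to_round)
  first |>
    select("trial_id", "vignette_id", "condition", "clinician_id",
           initial_estimate = "estimate", initial_accuracy = "accuracy",
           initial_correct = "correct") |>
    inner_join(
      last |>
        select("trial_id", "clinician_id", final_estimate = "estimate",
               final_accuracy = "accuracy", final_correct = "correct"),
      by = c("trial_id", "clinician_id")
    ) |>
    mutate(
      change_accuracy = 100 * (.data$final_accuracy - .data$initial_accuracy),
      revision_magnitude = abs(.data$final_estimate - .data$initial_estimate)
    )
}

#' Group clinicians into equal-frequency bins of initial accuracy
#'
#' Rank-based binning on round-1 accuracy: bin 1 holds the least accurate
#' clinicians, bin `k` the most accurate (the quartile and decile groupings
#' of the differential analyses). By default clinicians are pooled across
#' all trials of their condition before binning; `scope = "trial"` bins
#' within each trial instead. Ties are broken by the stable order
#' (accuracy, trial id, clinician id), so the assignment is deterministic,
#' every clinician lands in exactly one bin, and bin sizes differ by at
#' most one.
#'
#' @param clinicians Output of [clinician_summary()] (needs
#'   `initial_accuracy`, `trial_id`, `clinician_id`, `condition`).
#' @param k Number of bins (4 for quartiles, 10 for deciles).
#' @param scope `"condition"` (default) or `"trial"`.
#' @return The input with an integer `bin` column added.
#' @export
bin_by_initial_accuracy <- function(clinicians, k = 4L,
                                    scope = c("condition", "trial")) {
  scope <- match.arg(scope)
  check_scalar_number(k, "k", lo = 2)
  group_vars <- if (scope == "condition") "condition" else c("condition", "trial_id")
  out <- clinicians |>
    group_by(across(all_of(group_vars))) |>
    group_modify(function(df, key) {
      if (nrow(df) < k) {
        abort(sprintf("fewer clinicians (%d) than bins (%d).", nrow(df), k),
              class = "netwisdom_invalid_parameters")
      }
      ord <- order(df$initial_accuracy, df$trial_id, df$clinician_id)
      bin <- integer(nrow(df))
      bin[ord] <- floor((seq_len(nrow(df)) - 1) * k / nrow(df)) + 1L
      df$bin <- bin
      df
    }) |>
    ungroup()
  out
}

#' Trial-level mean accuracy at one round
#'
#' The trial is the unit of inference (clinicians within a networked trial
#' are not independent): this returns the mean normalized accuracy across a
#' trial's clinicians at the given round.
#'
#' @param responses Response tibble for a single trial.
#' @param truth Correct risk value for the trial's vignette.
#' @param round Round number.
#' @param bounds Normalization bounds, as in [accuracy_from_error()].
#' @return Mean accuracy in `[0, 1]`.
#' @export
trial_mean_accuracy <- function(responses, truth, round, bounds = c(-100, 0)) {
  rows <- responses[responses$round == round, ]
  clinicians <- unique(responses$clinician_id)
  if (!setequal(rows$clinician_id, clinicians) || nrow(rows) != length(clinicians)) {
    abort(sprintf("incomplete panel at round %d.", round),
          class = "netwisdom_missing_data")
  }
  mean(accuracy_from_error(absolute_error(rows$estimate, truth), bounds = bounds))
}

#' Mean change in accuracy between two rounds
#'
#' Mean accuracy at `to_round` minus mean accuracy at `from_round`, averaged
#' over the clinicians present in the panel (filter the panel first to
#' restrict to a condition, quartile, or trial), reported in percentage
#' points on the 0-100 scale.
#'
#' @param panel Output of [accuracy_panel()] (optionally filtered).
#' @param from_round,to_round Rounds compared.
#' @return Scalar change in percentage points.
#' @export
change_in_accuracy <- function(panel, from_round = 1L, to_round = 3L) {
  missing_rounds <- setdiff(c(from_round, to_round), unique(panel$round))
  if (length(missing_rounds) > 0) {
    abort(sprintf("round %s not present in panel.", missing_rounds),
          class = "netwisdom_invalid_parameters")
  }
  m_from <- mean(panel$accuracy[panel$round == from_round])
  m_to <- mean(panel$accuracy[panel$round == to_round])
  100 * (m_to - m_from)
}

#' Revision magnitude per clinician
#'
#' The absolute change in a clinician's raw risk estimate between their
#' initial and final response, in percentage points.
#'
#' @param panel Output of [accuracy_panel()].
#' @param from_round,to_round Rounds compared (defaults 1 and 3).
#' @return Tibble `trial_id`, `clinician_id`, `revision_magnitude`.
#' @export
revision_magnitude <- function(panel, from_round = 1L, to_round = 3L) {
  missing_rounds <- setdiff(c(from_round, to_round), unique(panel$round))
  if (length(missing_rounds) > 0) {
    abort(sprintf("round %s not present in panel.", missing_rounds),
          class = "netwisdom_missing_data")
  }
  panel |>
    filter(.data$round %in% c(from_round, to_round)) |>
    select("trial_id", "clinician_id", "round", "estimate") |>
    pivot_wider(names_from = "round", values_from = "estimate",
                names_prefix = "r") |>
    mutate(revision_magnitude = abs(.data[[paste0("r", to_round)]] -
                                      .data[[paste0("r", from_round)]])) |>
    select("trial_id", "clinician_id", "revision_magnitude")
}

#' Fraction of a trial's clinicians choosing the correct recommendation
#'
#' @param responses Response tibble for a single trial.
#' @param round Round number.
#' @param correct_option The vignette's evidence-based recommendation.
#' @return Fraction in `[0, 1]`.
#' @export
correct_rate <- function(responses, round, correct_option) {
  rows <- responses[responses$round == round, ]
  mean(rows$recommendation == correct_option)
}

#' Recommendation switch rates within a trial
#'
#' Among clinicians whose initial recommendation was incorrect, the fraction
#' whose final recommendation is correct (and the converse rate among the
#' initially correct). A rate whose eligibility set is empty is reported as
#' `NA`, not zero.
#'
#' @param panel Accuracy panel rows for one trial (needs the `correct`
#'   column from [accuracy_panel()]).
#' @param from_round,to_round Rounds compared (defaults 1 and 3).
#' @return One-row tibble: `incorrect_to_correct`, `correct_to_incorrect`,
#'   `n_initially_incorrect`, `n_initially_correct`.
#' @export
switch_rate <- function(panel, from_round = 1L, to_round = 3L) {
  cs <- clinician_summary(panel, from_round, to_round)
  inc <- cs[!cs$initial_correct, ]
  cor <- cs[cs$initial_correct, ]
  tibble(
    incorrect_to_correct = if (nrow(inc) > 0) mean(inc$final_correct) else NA_real_,
    correct_to_incorrect = if (nrow(cor) > 0) mean(!cor$final_correct) else NA_real_,
    n_initially_incorrect = nrow(inc),
    n_initially_correct = nrow(cor)
  )
}

#' Per-trial outcome summaries
#'
#' One row per trial with mean accuracy and correct-recommendation rate at
#' each round, plus the trial-level change scores used for inference:
#' accuracy changes from round 1 to 2 and 1 to the final round (percentage
#' points) and the change in correct-recommendation rate.
#'
#' @param panel Output of [accuracy_panel()].
#' @return Tibble, one row per trial.
#' @export
trial_summaries <- function(panel) {
  per_round <- panel |>
    group_by(.data$trial_id, .data$vignette_id, .data$condition, .data$round) |>
    summarise(
      mean_accuracy = mean(.data$accuracy),
      correct_rate = mean(.data$correct),
      .groups = "drop"
    )
  wide <- per_round |>
    pivot_wider(names_from = "round",
                values_from = c("mean_accuracy", "correct_rate"))
  last <- max(panel$round)
  wide |>
    mutate(
      change_accuracy_12 = 100 * (.data$mean_accuracy_2 - .data$mean_accuracy_1),
      change_accuracy_final = 100 * (.data[[paste0("mean_accuracy_", last)]] -
                                       .data$mean_accuracy_1),
      change_correct_final = .data[[paste0("correct_rate_", last)]] -
        .data$correct_rate_1
    )
}

#' Tabulate outcomes by condition and initial-accuracy quartile
#'
#' The summary table of the differential analysis: clinicians are pooled
#' across trials within each condition, grouped into quartiles of initial
#' accuracy (quartile 1 = least accurate), and averaged at the individual
#' level. Accuracy columns are on the 0-100 percent scale; recommendation
#' columns are rates in `[0, 1]`.
#'
#' @param panel Output of [accuracy_panel()].
#' @param k Number of bins (default 4).
#' @param scope Binning scope, see [bin_by_initial_accuracy()].
#' @return Tibble with `condition`, `quartile`, `n`, `initial_accuracy`,
#'   `final_accuracy`, `change_accuracy`, `initial_correct_rate`,
#'   `final_correct_rate`, `change_correct_rate`.
#' @export
tabulate_quartile_summary <- function(panel, k = 4L,
                                      scope = c("condition", "trial")) {
  clin <- clinician_summary(panel) |>
    bin_by_initial_accuracy(k = k, scope = scope)
  clin |>
    group_by(.data$condition, quartile = .data$bin) |>
    summarise(
      n = n(),
      initial_accuracy = 100 * mean(.data$initial_accuracy),
      final_accuracy = 100 * mean(.data$final_accuracy),
      change_accuracy = mean(.data$change_accuracy),
      initial_correct_rate = mean(.data$initial_correct),
      final_correct_rate = mean(.data$final_correct),
      change_correct_rate = mean(.data$final_correct) - mean(.data$initial_correct),
      .groups = "drop"
    ) |>
    arrange(.data$condition, .data$quartile)
}
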