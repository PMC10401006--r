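#' Configuration of a single experimental trial
#'
#' A trial administers one clinical vignette to one group of clinicians over
#' several response rounds, in either the `"network"` condition (each
#' participant sees their neighbours' mean risk estimate before revising) or
#' the independent `"control"` condition. Each round a clinician provides a
#' risk estimate on 0-100 and picks one categorical treatment recommendation.
#'
#' @param vignette_id Label of the clinical vignette.
#' @param condition `"network"` or `"control"`.
#' @param truth Correct risk estimate for the vignette, in `[0, 100]`.
#' @param options Ordered character vector of recommendation labels.
#' @param correct_option The evidence-based recommendation; must be one of
#'   `options`. Defaults to the option implied by `truth` under `thresholds`.
#' @param thresholds Strictly increasing cut-points on `[0, 100]` mapping a
#'   risk estimate to a recommendation; length `length(options) - 1`.
#' @param n_clinicians Clinicians per trial (study default 40).
#' @param n_rounds Response rounds (study default 3; at least 2).
#' @return A `trial_config` object (validated list).
#' @export
#' @examples
#' trial_config("v1", "network", truth = 60,
#'              options = c("discharge", "evaluate", "observe"),
#'              thresholds = c(35, 65))
trial_config <- function(vignette_id, condition = c("network", "control"),
                         truth, options, correct_option = NULL,
                         thresholds = NULL, n_clinicians = 40L, n_rounds = 3L) {
  condition <- match.arg(condition)
  check_scalar_number(truth, "truth", 0, 100)
  check_scalar_number(n_clinicians, "n_clinicians", lo = 1)
  check_scalar_number(n_rounds, "n_rounds", lo = 2)
  stopifnot(is.character(options), length(options) >= 2, !anyDuplicated(options))
  if (!is.null(thresholds)) {
    if (length(thresholds) != length(options) - 1 ||
        is.unsorted(thresholds, strictly = TRUE)) {
      abort("`thresholds` must be strictly increasing with length(options) - 1 cut-points.",
            class = "netwisdom_invalid_parameters")
    }
  }
  if (is.null(correct_option)) {
    if (is.null(thresholds)) {
      abort("supply either `correct_option` or `thresholds`.",
            class = "netwisdom_invalid_parameters")
    }
    correct_option <- map_recommendation(truth, thresholds, options)
  }
  if (!correct_option %in% options) {
    abort("`correct_option` must be one of `options`.",
          class = "netwisdom_invalid_parameters")
  }
  structure(
    list(
      vignette_id = as.character(vignette_id), condition = condition,
      truth = as.numeric(truth), options = options,
      correct_option = correct_option, thresholds = thresholds,
      n_clinicians = as.integer(n_clinicians), n_rounds = as.integer(n_rounds)
    ),
    class = "trial_config"
  )
}

#' Default panel of seven clinical vignettes
#'
#' Seven synthetic vignettes emulating the structure of the study's clinical
#' cases: each has an evidence-based correct risk value on 0-100, three
#' treatment options (e.g. discharge / admit for evaluation / admit to the
#' observation unit), and risk thresholds linking the estimate to the
#' recommended action. The truths span low- to high-risk cases so that
#' recommendation difficulty varies across vignettes; clinical narrative
#' content is out of scope.
#'
#' @return Tibble with columns `vignette_id`, `truth`, `correct_option`, and
#'   list-columns `options` and `thresholds`.
#' @export
default_vignettes <- function() {
  opts <- c("discharge", "evaluate", "observe")
  thr <- c(35, 65)
  truths <- c(15, 25, 40, 45, 60, 70, 85)
  tibble(
    vignette_id = sprintf("v%d", seq_along(truths)),
    truth = truths,
    options = rep(list(opts), length(truths)),
    thresholds = rep(list(thr), length(truths)),
    correct_option = vapply(truths, map_recommendation, character(1),
                            thresholds = thr, options = opts)
  )
}

#' Validate a trial's response panel against its configuration
#'
#' Checks the structural invariants of one trial: a complete panel (every
#' clinician has exactly one response per round), estimates within `[0, 100]`,
#' recommendations drawn from the vignette's options, and topology presence
#' consistent with the condition (present iff `"network"`, with one node per
#' clinician). Violations are returned, not raised.
#'
#' @param responses Tibble with columns `clinician_id`, `round`, `estimate`,
#'   `recommendation` for a single trial.
#' @param config A [trial_config()].
#' @param topology A [regular_network()] or `NULL`.
#' @return Tibble of violations with columns `rule` and `detail` (zero rows
#'   when the trial is well formed).
#' @export
validate_trial <- function(responses, config, topology = NULL) {
  stopifnot(inherits(config, "trial_config"))
  v <- list()
  add <- function(rule, detail) {
    v[[length(v) + 1]] <<- tibble(rule = rule, detail = detail)
  }

  counts <- responses |>
    count(.data$clinician_id, .data$round)
  if (any(counts$n > 1)) {
    dup <- counts[counts$n > 1, ]
    add("complete-panel",
        sprintf("clinician %s has %d responses at round %s",
                dup$clinician_id, dup$n, dup$round))
  }
  grid <- tidyr::expand_grid(
    clinician_id = unique(responses$clinician_id),
    round = seq_len(config$n_rounds)
  )
  missing <- anti_join(grid, counts, by = c("clinician_id", "round"))
  if (nrow(missing) > 0) {
    add("complete-panel",
        sprintf("clinician %s is missing round %d", missing$clinician_id, missing$round))
  }
  n_clin <- length(unique(responses$clinician_id))
  if (n_clin != config$n_clinicians) {
    add("panel-size",
        sprintf("%d clinicians present, expected %d", n_clin, config$n_clinicians))
  }
  bad_round <- !responses$round %in% seq_len(config$n_rounds)
  if (any(bad_round)) {
    add("round-range", sprintf("round %s outside 1..%d",
                               unique(responses$round[bad_round]), config$n_rounds))
  }
  bad_est <- !is.finite(responses$estimate) |
    responses$estimate < 0 | responses$estimate > 100
  if (any(bad_est)) {
    add("estimate-range",
        sprintf("clinician %s round %s estimate %s outside [0, 100]",
                responses$clinician_id[bad_est], responses$round[bad_est],
                responses$estimate[bad_est]))
  }
  bad_rec <- !responses$recommendation %in% config$options
  if (any(bad_rec)) {
    add("recommendation-label",
        sprintf("unknown recommendation '%s' for clinician %s",
                responses$recommendation[bad_rec], responses$clinician_id[bad_rec]))
  }
  if (config$condition == "network") {
    if (is.null(topology)) {
      add("topology-consistency", "network trial has no topology")
    } else if (topology$n_nodes != config$n_clinicians) {
      add("topology-consistency",
          sprintf("topology has %d nodes for %d clinicians",
                  topology$n_nodes, config$n_clinicians))
    }
  } else if (!is.null(topology)) {
    add("topology-consistency", "control trial carries a topology")
  }

  if (length(v) == 0) tibble(rule = character(), detail = character()) else bind_rows(v)
}
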