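#' Run the full trial-level analysis chain
#'
#' Executes the complete analytic pipeline on a study dataset: the accuracy
#' panel, per-trial summaries, between-condition baseline and improvement
#' contrasts (Wilcoxon rank-sum at the trial level), within-condition
#' improvement tests (Wilcoxon signed-rank, paired at the trial level),
#' quartile differential contrasts with Hodges-Lehmann intervals, the
#' decile revision trend in the network arm (Jonckheere-Terpstra), the
#' recommendation analyses (trial-level correct-rate changes, switch rates
#' by quartile, the least-accurate-quartile switch contrast by Student t,
#' and the Spearman correlation between accuracy improvement and switching
#' to the correct recommendation), and the condition-by-quartile summary
#' table. All inference is at the trial level except where noted, because
#' clinicians within a networked trial are not independent.
#'
#' @param study A `ci_study` from [simulate_study()], or a list with
#'   elements `responses` and `vignettes` (e.g. data read from files).
#' @param norm Accuracy normalization, `"fixed"` or `"observed"`
#'   (see [accuracy_panel()]).
#' @param binning Quartile/decile binning scope, `"condition"` (pooled,
#'   default) or `"trial"` (mapped to [bin_by_initial_accuracy()] scopes).
#' @param jt_mode,jt_n_perm Mode and permutation count for the
#'   Jonckheere-Terpstra trend test.
#' @param seed Seed for the analysis's own randomness (permutation nulls).
#' @return A `ci_analysis` object: list of tibbles (`overall`,
#'   `trial_summaries`, `quartile_contrasts`, `quartile_table`,
#'   `decile_revision`, `switch_summary`, `tests`) plus the options used.
#' @export
run_analyze <- function(study,
                        norm = c("fixed", "observed"),
                        binning = c("condition", "trial"),
                        jt_mode = "auto", jt_n_perm = 10000L,
                        seed = 1L) {
  norm <- match.arg(norm)
  binning <- match.arg(binning)
  responses <- study$responses
  vignettes <- study$vignettes
  panel <- accuracy_panel(responses, vignettes, norm = norm)
  trials <- trial_summaries(panel)
  clin <- clinician_summary(panel)

  tests <- list()
  note <- function(label, test) {
    tests[[length(tests) + 1]] <<- mutate(tidy(test), label = label,
                                          .before = 1)
    test
  }

  net <- trials[trials$condition == "network", ]
  ctl <- trials[trials$condition == "control", ]
  both_arms <- nrow(net) > 0 && nrow(ctl) > 0

  # Overall accuracy: baseline equivalence, within-condition improvement,
  # between-condition improvement contrast (all trial-level).
  overall <- trials |>
    group_by(.data$condition) |>
    summarise(
      n_trials = n(),
      initial_accuracy = 100 * mean(.data$mean_accuracy_1),
      final_accuracy = 100 * mean(.data[[paste0("mean_accuracy_", max(panel$round))]]),
      improvement = mean(.data$change_accuracy_final),
      initial_correct_rate = mean(.data$correct_rate_1),
      final_correct_rate = mean(.data[[paste0("correct_rate_", max(panel$round))]]),
      correct_rate_change = mean(.data$change_correct_final),
      .groups = "drop"
    )
  if (both_arms) {
    note("baseline accuracy, network vs control",
         wilcoxon_rank_sum(net$mean_accuracy_1, ctl$mean_accuracy_1))
    note("accuracy improvement, network vs control",
         wilcoxon_rank_sum(net$change_accuracy_final, ctl$change_accuracy_final))
  }
  for (cond in unique(trials$condition)) {
    ch <- trials$change_accuracy_final[trials$condition == cond]
    if (length(ch) >= 1 && any(ch != 0)) {
      note(sprintf("within-%s accuracy improvement", cond),
           wilcoxon_signed_rank(ch))
    }
    cr <- trials$change_correct_final[trials$condition == cond]
    if (length(cr) >= 1 && any(cr != 0)) {
      note(sprintf("within-%s correct-recommendation improvement", cond),
           wilcoxon_signed_rank(cr))
    }
  }

  # Quartile differential contrasts (network - control change in accuracy),
  # at both the trial level and the clinician level; the trial level is the
  # primary inference scale.
  clin_q <- bin_by_initial_accuracy(clin, k = 4L, scope = binning)
  quartile_contrasts <- list()
  for (to in c("12", "final")) {
    to_round <- if (to == "12") 2L else max(panel$round)
    chg <- clinician_summary(panel, 1L, to_round) |>
      select("trial_id", "clinician_id", "change_accuracy") |>
      rename(chg = "change_accuracy") |>
      inner_join(clin_q |> select("trial_id", "clinician_id", "condition", "bin"),
                 by = c("trial_id", "clinician_id"))
    for (q in sort(unique(clin_q$bin))) {
      qq <- chg[chg$bin == q, ]
      trial_chg <- qq |>
        group_by(.data$trial_id, .data$condition) |>
        summarise(chg = mean(.data$chg), .groups = "drop")
      for (level in c("trial", "clinician")) {
        dat <- if (level == "trial") trial_chg else qq
        x <- dat$chg[dat$condition == "control"]
        y <- dat$chg[dat$condition == "network"]
        if (length(x) == 0 || length(y) == 0) next
        ci <- rank_sum_ci(x, y)
        p <- wilcoxon_rank_sum(y, x)$p_value
        quartile_contrasts[[length(quartile_contrasts) + 1]] <- tibble(
          quartile = q, rounds = paste0("1-", to_round), level = level,
          mean_change_network = mean(y), mean_change_control = mean(x),
          difference = ci$estimate, conf_low = ci$conf_low,
          conf_high = ci$conf_high, p_value = p,
          n_network = length(y), n_control = length(x)
        )
      }
    }
  }
  quartile_contrasts <- bind_rows(quartile_contrasts)

  # Decile revision trend in the network arm: do initially accurate
  # clinicians revise less?
  net_clin <- clin[clin$condition == "network", ]
  decile_revision <- NULL
  jt <- NULL
  if (nrow(net_clin) >= 10) {
    net_dec <- bin_by_initial_accuracy(net_clin, k = 10L, scope = binning)
    decile_revision <- net_dec |>
      group_by(decile = .data$bin) |>
      summarise(
        n = n(),
        mean_initial_accuracy = 100 * mean(.data$initial_accuracy),
        mean_revision = mean(.data$revision_magnitude),
        se_revision = stats::sd(.data$revision_magnitude) / sqrt(n()),
        .groups = "drop"
      )
    groups <- split(net_dec$revision_magnitude, net_dec$bin)
    jt <- note("revision magnitude across initial-accuracy deciles (network)",
               jonckheere_terpstra(groups, alternative = "two.sided",
                                   mode = jt_mode, n_perm = jt_n_perm,
                                   seed = split_seed(seed, 101L)))
  }

  # Recommendation switching: per condition x quartile incorrect-to-correct
  # rates; the least-accurate quartile contrast uses a Student t test, and
  # switching is correlated with accuracy improvement by Spearman.
  switch_clin <- clin_q |>
    filter(!.data$initial_correct) |>
    mutate(switched = .data$final_correct)
  switch_summary <- switch_clin |>
    group_by(.data$condition, quartile = .data$bin) |>
    summarise(
      n_eligible = n(),
      incorrect_to_correct = mean(.data$switched),
      .groups = "drop"
    )
  if (both_arms && nrow(switch_clin) > 0) {
    q1 <- switch_clin[switch_clin$bin == 1, ]
    q1_trial <- q1 |>
      group_by(.data$trial_id, .data$condition) |>
      summarise(rate = mean(.data$switched), .groups = "drop")
    xq <- q1_trial$rate[q1_trial$condition == "network"]
    yq <- q1_trial$rate[q1_trial$condition == "control"]
    if (length(xq) >= 2 && length(yq) >= 2 &&
        (stats::var(xq) > 0 || stats::var(yq) > 0)) {
      note("Q1 incorrect-to-correct switching, network vs control (t)",
           two_sample_t(xq, yq, var_equal = TRUE))
    }
    if (stats::sd(switch_clin$change_accuracy) > 0 &&
        stats::sd(as.numeric(switch_clin$switched)) > 0) {
      note("accuracy improvement vs switching to correct (Spearman)",
           spearman_cor(switch_clin$change_accuracy,
                        as.numeric(switch_clin$switched)))
    }
  }

  structure(
    list(
      overall = overall,
      trial_summaries = trials,
      quartile_contrasts = quartile_contrasts,
      quartile_table = tabulate_quartile_summary(panel, scope = binning),
      decile_revision = decile_revision,
      switch_summary = switch_summary,
      tests = bind_rows(tests),
      options = list(norm = norm, binning = binning, jt_mode = jt_mode,
                     jt_n_perm = jt_n_perm, seed = as.integer(seed)),
      exclusions = attr(panel, "exclusions")
    ),
    class = "ci_analysis"
  )
}

#' @export
print.ci_analysis <- function(x, ...) {
  cat("<ci_analysis>\n")
  print(x$overall)
  cat(sprintf("  %d tests, %d quartile contrasts; options: norm=%s, binning=%s\n",
              nrow(x$tests), nrow(x$quartile_contrasts),
              x$options$norm, x$options$binning))
  invisible(x)
}

#' @export
#' @method tidy ci_analysis
tidy.ci_analysis <- function(x, ...) x$tests

#' @export
#' @method glance ci_analysis
glance.ci_analysis <- function(x, ...) {
  imp <- x$overall
  net <- imp[imp$condition == "network", ]
  ctl <- imp[imp$condition == "control", ]
  tibble(
    n_trials = sum(imp$n_trials),
    improvement_network = if (nrow(net)) net$improvement else NA_real_,
    improvement_control = if (nrow(ctl)) ctl$improvement else NA_real_,
    n_tests = nrow(x$tests)
  )
}

fmt_table <- function(df, digits = 3) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
  }
  utils::capture.output(print(df, row.names = FALSE))
}

#' Render a plain-text report from an analysis bundle
#'
#' Writes a human-readable report: overall condition summary, the
#' condition-by-quartile outcome table, the quartile differential
#' contrasts, the decile revision table, the recommendation-switch table,
#' and the full test report. Rendering is deterministic: the same bundle
#' always yields byte-identical output.
#'
#' @param analysis A `ci_analysis` from [run_analyze()].
#' @param path Optional file to write; when `NULL` the lines are returned
#'   only.
#' @return Character vector of report lines, invisibly when `path` is
#'   given.
#' @export
run_report <- function(analysis, path = NULL) {
  stopifnot(inherits(analysis, "ci_analysis"))
  required <- c("overall", "quartile_table", "quartile_contrasts",
                "switch_summary", "tests")
  missing <- required[vapply(required, function(f) is.null(analysis[[f]]), logical(1))]
  if (length(missing) > 0) {
    abort(sprintf("incomplete results bundle: missing stage '%s'.", missing[1]),
          class = "netwisdom_invalid_input")
  }
  sect <- function(title, tbl) {
    c(title, strrep("-", nchar(title)), fmt_table(tbl), "")
  }
  lines <- c(
    "Networked collective intelligence analysis report",
    "=================================================",
    sprintf("options: norm=%s, binning=%s, jt_mode=%s, seed=%d",
            analysis$options$norm, analysis$options$binning,
            analysis$options$jt_mode, analysis$options$seed),
    "",
    sect("Overall condition summary (accuracy in %, changes in points)",
         analysis$overall),
    sect("Outcomes by condition and initial-accuracy quartile (1 = least accurate)",
         analysis$quartile_table),
    sect("Quartile differential contrasts (network - control)",
         analysis$quartile_contrasts),
    if (!is.null(analysis$decile_revision)) {
      sect("Revision magnitude by initial-accuracy decile (network arm)",
           analysis$decile_revision)
    },
    sect("Incorrect-to-correct recommendation switching", analysis$switch_summary),
    sect("Statistical tests", analysis$tests)
  )
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
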