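#' @importFrom ggplot2 ggplot aes geom_point geom_errorbar geom_pointrange
#'   geom_col geom_hline facet_wrap labs position_dodge autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot quartile differential contrasts
#'
#' Point-range plot of the network-minus-control difference in accuracy
#' change within each initial-accuracy quartile, with the rank-sum-inverted
#' confidence intervals (the figure-2-style differential analysis).
#'
#' @param contrasts The `quartile_contrasts` tibble of a `ci_analysis`.
#' @param level `"trial"` (default) or `"clinician"`.
#' @return A ggplot object.
#' @export
plot_quartile_contrasts <- function(contrasts, level = "trial") {
  dat <- contrasts[contrasts$level == level, ]
  ggplot(dat, aes(x = factor(.data$quartile), y = .data$difference,
                  colour = .data$rounds)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_pointrange(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                    position = position_dodge(width = 0.4)) +
    labs(x = "Initial-accuracy quartile (1 = least accurate)",
         y = "Difference in accuracy change, network - control (points)",
         colour = "Rounds")
}

#' Plot revision magnitude by initial-accuracy decile
#'
#' Mean revision magnitude (with +/- 1 SE bars) across deciles of initial
#' accuracy in the network arm; a downward trend is the revision-coefficient
#' signature (accurate clinicians revise less).
#'
#' @param decile_revision The `decile_revision` tibble of a `ci_analysis`.
#' @return A ggplot object.
#' @export
plot_decile_revision <- function(decile_revision) {
  ggplot(decile_revision, aes(x = factor(.data$decile), y = .data$mean_revision)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean_revision - .data$se_revision,
                      ymax = .data$mean_revision + .data$se_revision),
                  width = 0.2) +
    labs(x = "Initial-accuracy decile (1 = least accurate)",
         y = "Mean revision magnitude (points)")
}

#' Plot incorrect-to-correct switch rates by condition and quartile
#'
#' @param switch_summary The `switch_summary` tibble of a `ci_analysis`.
#' @return A ggplot object.
#' @export
plot_switch_rates <- function(switch_summary) {
  ggplot(switch_summary,
         aes(x = factor(.data$quartile), y = .data$incorrect_to_correct,
             fill = .data$condition)) +
    geom_col(position = position_dodge()) +
    labs(x = "Initial-accuracy quartile (1 = least accurate)",
         y = "Fraction switching incorrect -> correct",
         fill = "Condition")
}

#' @export
#' @method autoplot ci_analysis
autoplot.ci_analysis <- function(object, type = c("quartiles", "deciles", "switching"),
                                 ...) {
  type <- match.arg(type)
  switch(type,
    quartiles = plot_quartile_contrasts(object$quartile_contrasts, ...),
    deciles = plot_decile_revision(object$decile_revision),
    switching = plot_switch_rates(object$switch_summary)
  )
}
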