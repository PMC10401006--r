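#' Generator configuration for synthetic clinician cohorts
#'
#' Parameterizes the synthetic-data generator that emulates the three-round
#' experiment: heterogeneous initial skill, DeGroot-style revision toward
#' the displayed neighbour mean with an accuracy-dependent self-weight in
#' the network arm, and independent partial shrinkage toward the truth
#' ("independent reflection") in the control arm.
#'
#' Defaults (all on the 0-100 risk scale unless noted):
#' * `bias_spread = 29`: SD of each clinician's systematic offset from the
#'   truth. Together with `noise_sd` it yields a wide spread of initial
#'   accuracy across clinicians (quartile means of initial accuracy roughly
#'   from the high 40s to the high 90s on the percent scale).
#' * `noise_sd = 5`: SD of round-level response noise on the initial estimate.
#' * `stubbornness_base = 0.3`: baseline self-weight in the revision rule.
#' * `alpha_link = 0.6`: strength of the accuracy-to-stubbornness coupling;
#'   positive values make initially accurate clinicians revise less, which
#'   is the mechanism granting them greater de facto influence.
#' * `control_gain = 0.055`: per-round fractional shrinkage of a control
#'   clinician's estimate toward the truth, sized so that independent
#'   reflection yields a modest (2-3 point) accuracy improvement over two
#'   revision rounds.
#' * `control_noise_sd = 2`: SD of round-level noise on control revisions.
#'
#' @param bias_spread,noise_sd,stubbornness_base,alpha_link,control_gain,control_noise_sd
#'   See Details.
#' @return A `generator_config` object (validated list).
#' @export
generator_config <- function(bias_spread = 29, noise_sd = 5,
                             stubbornness_base = 0.3, alpha_link = 0.6,
                             control_gain = 0.055, control_noise_sd = 2) {
  check_scalar_number(bias_spread, "bias_spread", lo = 0)
  check_scalar_number(noise_sd, "noise_sd", lo = 0)
  check_scalar_number(stubbornness_base, "stubbornness_base", 0, 1)
  check_scalar_number(alpha_link, "alpha_link", lo = 0)
  check_scalar_number(control_gain, "control_gain", 0, 1)
  check_scalar_number(control_noise_sd, "control_noise_sd", lo = 0)
  structure(
    list(
      bias_spread = bias_spread, noise_sd = noise_sd,
      stubbornness_base = stubbornness_base, alpha_link = alpha_link,
      control_gain = control_gain, control_noise_sd = control_noise_sd
    ),
    class = "generator_config"
  )
}

#' Draw clinician skill profiles and initial estimates
#'
#' Each clinician has a persistent systematic bias (drawn from a centred
#' normal with SD `bias_spread`) plus independent round-level noise; the
#' initial estimate is `truth + bias + noise` clipped to `[0, 100]`. The
#' heavy bias spread produces the heterogeneity in initial accuracy that the
#' quartile and decile analyses rely on.
#'
#' @param n Number of clinicians.
#' @param truth Correct risk value in `[0, 100]`.
#' @param config A [generator_config()].
#' @return Tibble with one row per clinician: `bias`, `noise_sd`,
#'   `stubbornness_base`, `estimate`.
#' @export
sample_initial_estimates <- function(n, truth, config = generator_config()) {
  check_scalar_number(n, "n", lo = 1)
  check_scalar_number(truth, "truth", 0, 100)
  bias <- stats::rnorm(n, 0, config$bias_spread)
  noise <- stats::rnorm(n, 0, config$noise_sd)
  tibble(
    bias = bias,
    noise_sd = config$noise_sd,
    stubbornness_base = config$stubbornness_base,
    estimate = clip_unit_interval(truth + bias + noise)
  )
}

#' Self-weight in the revision rule as a function of initial accuracy
#'
#' Operationalizes the empirical revision-accuracy link: accurate
#' individuals revise their responses less. The self-weight is
#' `clip(stubbornness_base + alpha_link * (1 - initial_error / 100), 0, 1)`,
#' non-increasing in the initial error whenever `alpha_link > 0`.
#'
#' @param initial_error Absolute round-1 error(s) in percentage points,
#'   in `[0, 100]`.
#' @param config A [generator_config()].
#' @return Numeric self-weight(s) in `[0, 1]`.
#' @export
stubbornness <- function(initial_error, config = generator_config()) {
  if (any(initial_error < 0 | initial_error > 100)) {
    abort("`initial_error` must lie in [0, 100].",
          class = "netwisdom_invalid_parameters")
  }
  clip_unit_interval(
    config$stubbornness_base + config$alpha_link * (1 - initial_error / 100),
    lo = 0, hi = 1
  )
}

#' DeGroot-style revision toward the displayed neighbour mean
#'
#' Networked participants revise to a convex combination of their own
#' current estimate and the peer signal (their neighbours' mean estimate):
#' `w * current + (1 - w) * peer_mean`, clipped to `[0, 100]`.
#'
#' @param current Current estimate(s).
#' @param peer_mean Displayed neighbour-mean estimate(s).
#' @param w Self-weight(s) in `[0, 1]`.
#' @return Revised estimate(s).
#' @export
#' @examples
#' network_revision(40, 60, w = 0.25) # 55
network_revision <- function(current, peer_mean, w) {
  if (any(w < 0 | w > 1)) {
    abort("`w` must lie in [0, 1].", class = "netwisdom_invalid_parameters")
  }
  clip_unit_interval(w * current + (1 - w) * peer_mean)
}

#' Independent-reflection revision in the control arm
#'
#' Control clinicians revise without social information; re-reading the
#' vignette nudges the estimate a fraction `control_gain` of the way toward
#' the truth, plus round-level noise:
#' `current + control_gain * (truth - current) + noise`, clipped.
#'
#' @param current Current estimate(s).
#' @param truth Correct risk value.
#' @param config A [generator_config()].
#' @return Revised estimate(s).
#' @export
control_revision <- function(current, truth, config = generator_config()) {
  noise <- stats::rnorm(length(current), 0, config$control_noise_sd)
  clip_unit_interval(current + config$control_gain * (truth - current) + noise)
}

#' Map a risk estimate to a categorical treatment recommendation
#'
#' The treatment decision is driven by the underlying risk estimate through
#' ordered thresholds: option `k + 1` is chosen when `k` thresholds are at
#' or below the estimate. An estimate exactly at a threshold maps to the
#' higher-index option (fixed boundary convention).
#'
#' @param estimate Risk estimate(s) in `[0, 100]`.
#' @param thresholds Strictly increasing cut-points.
#' @param options Ordered recommendation labels, `length(thresholds) + 1`.
#' @return Character recommendation(s).
#' @export
#' @examples
#' map_recommendation(c(5, 35, 95), thresholds = c(10, 30),
#'                    options = c("low", "mid", "high"))
map_recommendation <- function(estimate, thresholds, options) {
  if (is.unsorted(thresholds, strictly = TRUE) ||
      length(options) != length(thresholds) + 1) {
    abort("`thresholds` must be strictly increasing with length(options) - 1 cut-points.",
          class = "netwisdom_invalid_parameters")
  }
  k <- vapply(estimate, function(e) sum(thresholds <= e), integer(1))
  options[k + 1L]
}

#' Simulate one trial of the three-round experiment
#'
#' Generates a complete response panel for one trial. Round 1 draws initial
#' estimates from the skill model. In the network condition, clinicians are
#' randomly assigned to topology nodes; each revision round replaces a
#' clinician's estimate with a convex combination of their current estimate
#' and their neighbours' mean estimate from the previous round (self-weight
#' from [stubbornness()], computed once from the round-1 error). In the
#' control condition each revision round applies [control_revision()]
#' independently. Recommendations are recomputed from each round's estimate.
#'
#' @param config A [trial_config()].
#' @param gen_config A [generator_config()].
#' @param topology A [regular_network()]; required iff the condition is
#'   `"network"`.
#' @param seed Optional integer seed.
#' @param trial_id Label stamped on the output rows.
#' @return Tibble with `n_clinicians * n_rounds` rows and columns
#'   `trial_id`, `vignette_id`, `condition`, `clinician_id`, `round`,
#'   `estimate`, `recommendation`. The node assignment of a network trial is
#'   attached as attribute `node_assignment`.
#' @export
simulate_trial <- function(config, gen_config = generator_config(),
                           topology = NULL, seed = NULL, trial_id = "t1") {
  stopifnot(inherits(config, "trial_config"))
  network <- config$condition == "network"
  if (network && is.null(topology)) {
    abort("network trials require a topology.", class = "netwisdom_invalid_parameters")
  }
  if (network && topology$n_nodes != config$n_clinicians) {
    abort("topology size must equal the number of clinicians.",
          class = "netwisdom_invalid_parameters")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_clinicians
  rounds <- config$n_rounds

  profiles <- sample_initial_estimates(n, config$truth, gen_config)
  est <- matrix(NA_real_, nrow = n, ncol = rounds)
  est[, 1] <- profiles$estimate
  w <- stubbornness(abs(est[, 1] - config$truth), gen_config)

  node_of <- NULL
  if (network) {
    node_of <- sample.int(n) - 1L # clinician i sits at node node_of[i]
    nb <- neighbor_list(topology)
  }
  for (r in 2:rounds) {
    if (network) {
      by_node <- numeric(n)
      by_node[node_of + 1L] <- est[, r - 1] # previous-round estimate at each node
      peers <- peer_signal_all(nb, by_node)[node_of + 1L]
      est[, r] <- network_revision(est[, r - 1], peers, w)
    } else {
      est[, r] <- control_revision(est[, r - 1], config$truth, gen_config)
    }
  }

  out <- tibble(
    trial_id = trial_id,
    vignette_id = config$vignette_id,
    condition = config$condition,
    clinician_id = rep(sprintf("%s_c%02d", trial_id, seq_len(n)), rounds),
    round = rep(seq_len(rounds), each = n),
    estimate = as.vector(est),
    recommendation = map_recommendation(as.vector(est), config$thresholds, config$options)
  )
  if (network) attr(out, "node_assignment") <- node_of
  out
}

#' Simulate a full multi-vignette study
#'
#' Runs the default study design — 7 vignettes, each administered in 8
#' network trials and 4 control trials of 40 clinicians (84 trials, giving
#' 56 network and 28 control trial-level observations) — with one canonical
#' degree-4 topology shared by all network trials. Every trial draws from
#' its own RNG stream derived from the master seed via [split_seed()], so
#' the dataset is reproducible bit-for-bit and adding trials or vignettes
#' never perturbs earlier trials.
#'
#' @param vignettes Vignette table as from [default_vignettes()].
#' @param trials_network,trials_control Trials per vignette per condition
#'   (study defaults 8 and 4).
#' @param gen_config A [generator_config()].
#' @param topology Topology shared by all network trials; defaults to
#'   [canonical_topology()] sized to `n_clinicians`.
#' @param n_clinicians,n_rounds Panel dimensions (defaults 40 and 3).
#' @param seed Master seed.
#' @return A `ci_study` object: list with `responses` (long tibble),
#'   `trials` (trial metadata), `vignettes`, `topology`, `gen_config`,
#'   `seed`.
#' @export
#' @examples
#' study <- simulate_study(trials_network = 1, trials_control = 1, seed = 1,
#'                         vignettes = default_vignettes()[1:2, ])
#' nrow(study$responses) # 4 trials x 40 clinicians x 3 rounds
simulate_study <- function(vignettes = default_vignettes(),
                           trials_network = 8L, trials_control = 4L,
                           gen_config = generator_config(),
                           topology = NULL,
                           n_clinicians = 40L, n_rounds = 3L, seed = 1L) {
  check_scalar_number(trials_network, "trials_network", lo = 0)
  check_scalar_number(trials_control, "trials_control", lo = 0)
  if (is.null(topology) && trials_network > 0) {
    topology <- if (n_clinicians == 40L) canonical_topology() else
      regular_network(n_clinicians, 4L, seed = CANONICAL_TOPOLOGY_SEED)
  }

  # Stable per-trial stream indices: vignette block of 1000, control trials
  # offset by 500, so extending either arm never reseeds existing trials.
  trials <- purrr::pmap(
    list(seq_len(nrow(vignettes)), vignettes$vignette_id),
    function(vi, vid) {
      bind_rows(
        if (trials_network > 0) tibble(
          vignette_id = vid, condition = "network",
          replicate = seq_len(trials_network),
          stream = (vi - 1L) * 1000L + seq_len(trials_network)
        ),
        if (trials_control > 0) tibble(
          vignette_id = vid, condition = "control",
          replicate = seq_len(trials_control),
          stream = (vi - 1L) * 1000L + 500L + seq_len(trials_control)
        )
      )
    }
  ) |> list_rbind()
  trials <- trials |>
    mutate(
      trial_id = sprintf("%s_%s_%02d", .data$vignette_id,
                         substr(.data$condition, 1, 3), .data$replicate),
      seed = split_seed(seed, .data$stream)
    )

  vlookup <- stats::setNames(seq_len(nrow(vignettes)), vignettes$vignette_id)
  responses <- purrr::pmap(
    trials[c("trial_id", "vignette_id", "condition", "seed")],
    function(trial_id, vignette_id, condition, seed) {
      vrow <- vignettes[vlookup[[vignette_id]], ]
      cfg <- trial_config(
        vignette_id, condition, truth = vrow$truth,
        options = vrow$options[[1]], thresholds = vrow$thresholds[[1]],
        correct_option = vrow$correct_option,
        n_clinicians = n_clinicians, n_rounds = n_rounds
      )
      simulate_trial(cfg, gen_config,
                     topology = if (condition == "network") topology,
                     seed = seed, trial_id = trial_id)
    }
  ) |> list_rbind()

  structure(
    list(
      responses = responses,
      trials = trials[c("trial_id", "vignette_id", "condition", "replicate", "seed")],
      vignettes = vignettes, topology = topology,
      gen_config = gen_config, seed = as.integer(seed)
    ),
    class = "ci_study"
  )
}

#' @export
print.ci_study <- function(x, ...) {
  tab <- table(x$trials$condition)
  cat(sprintf(
    "<ci_study> %d trials (%s), %d vignettes, %d response rows, master seed %d\n",
    nrow(x$trials),
    paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
    nrow(x$vignettes), nrow(x$responses), x$seed
  ))
  invisible(x)
}
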