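# Fixtures built in code: tiny vignette tables and hand-sized response
# panels used across test files.

tiny_vignettes <- function(truths = c(30, 60)) {
  opts <- c("low", "mid", "high")
  thr <- c(25, 50)
  tibble::tibble(
    vignette_id = sprintf("v%d", seq_along(truths)),
    truth = truths,
    options = rep(list(opts), length(truths)),
    thresholds = rep(list(thr), length(truths)),
    correct_option = vapply(truths, netwisdom::map_recommendation,
                            character(1), thresholds = thr, options = opts)
  )
}

# A hand-built single-trial panel: estimates chosen so errors, quartiles
# and switches can be verified by hand. One row per clinician per round.
hand_panel_responses <- function(trial_id = "t1", vignette_id = "v1",
                                 condition = "control",
                                 estimates_by_round,
                                 thresholds = c(25, 50),
                                 options = c("low", "mid", "high")) {
  # estimates_by_round: matrix, clinicians x rounds
  n <- nrow(estimates_by_round)
  rounds <- ncol(estimates_by_round)
  tibble::tibble(
    trial_id = trial_id,
    vignette_id = vignette_id,
    condition = condition,
    clinician_id = rep(sprintf("c%02d", seq_len(n)), rounds),
    round = rep(seq_len(rounds), each = n),
    estimate = as.vector(estimates_by_round),
    recommendation = netwisdom::map_recommendation(
      as.vector(estimates_by_round), thresholds, options)
  )
}

# A generator configuration with all randomness and dynamics switched off:
# estimates equal the truth and never move.
frozen_generator <- function() {
  netwisdom::generator_config(
    bias_spread = 0, noise_sd = 0, stubbornness_base = 1, alpha_link = 0,
    control_gain = 0, control_noise_sd = 0
  )
}

# Small study used where full scale is unnecessary.
small_study <- function(seed = 1, gen = netwisdom::generator_config(),
                        trials_network = 2, trials_control = 2,
                        truths = c(30, 60)) {
  netwisdom::simulate_study(
    vignettes = tiny_vignettes(truths),
    trials_network = trials_network, trials_control = trials_control,
    gen_config = gen, seed = seed
  )
}
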