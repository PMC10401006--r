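# Plain-text interchange formats:
#   responses: trial_id,vignette_id,condition,clinician_id,round,estimate,recommendation
#   edges:     trial_id,node_a,node_b  (one undirected edge per row, 0-based ids)
# plus a YAML study configuration and a JSON provenance manifest.

RESPONSE_COLUMNS <- c("trial_id", "vignette_id", "condition", "clinician_id",
                      "round", "estimate", "recommendation")

#' Write a response dataset to delimited text
#'
#' @param responses Long response tibble with the canonical columns.
#' @param path Output file (comma-delimited, with header).
#' @export
write_responses <- function(responses, path) {
  stopifnot(all(RESPONSE_COLUMNS %in% names(responses)))
  readr::write_csv(responses[RESPONSE_COLUMNS], path)
  invisible(path)
}

#' Read and validate a response dataset
#'
#' Reads the canonical response schema and screens every row: estimates
#' must lie in `[0, 100]`, rounds must be positive integers, conditions
#' must be `network` or `control`, and (when a vignette table is supplied)
#' recommendation labels must belong to the vignette's options. Malformed
#' rows are dropped from the returned data and collected, with their line
#' numbers and a distinct issue tag, in the `problems` attribute.
#'
#' An external deposit with different column names can be ingested by
#' supplying `col_map`, a named character vector mapping canonical names to
#' the file's names, e.g. `c(clinician_id = "subject", estimate = "guess")`.
#'
#' @param path Delimited text file.
#' @param vignettes Optional vignette table for label validation.
#' @param col_map Optional importer hook: named character vector
#'   `canonical = external`.
#' @return Validated response tibble; rejected rows in
#'   `attr(, "problems")` (columns `line`, `issue`).
#' @export
read_responses <- function(path, vignettes = NULL, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(raw)) {
        abort(sprintf("mapped column '%s' not found in file.", col_map[[canon]]),
              class = "netwisdom_invalid_input")
      }
      names(raw)[names(raw) == col_map[[canon]]] <- canon
    }
  }
  missing <- setdiff(RESPONSE_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "netwisdom_missing_columns")
  }
  raw <- raw[RESPONSE_COLUMNS]
  line <- seq_len(nrow(raw)) + 1L # header is line 1

  est <- suppressWarnings(as.numeric(raw$estimate))
  rnd <- suppressWarnings(as.numeric(raw$round))
  issues <- list(
    tibble(line = line[is.na(est)], issue = "estimate-not-numeric"),
    tibble(line = line[!is.na(est) & (est < 0 | est > 100)],
           issue = "estimate-out-of-range"),
    tibble(line = line[is.na(rnd) | rnd != round(rnd) | rnd < 1],
           issue = "round-not-positive-integer"),
    tibble(line = line[!raw$condition %in% c("network", "control")],
           issue = "unknown-condition")
  )
  if (!is.null(vignettes)) {
    allowed <- vignettes |>
      select("vignette_id", "options") |>
      tidyr::unnest("options") |>
      rename(recommendation = "options")
    known_v <- raw$vignette_id %in% vignettes$vignette_id
    issues <- c(issues, list(
      tibble(line = line[!known_v], issue = "unknown-vignette")
    ))
    pair_ok <- paste(raw$vignette_id, raw$recommendation) %in%
      paste(allowed$vignette_id, allowed$recommendation)
    issues <- c(issues, list(
      tibble(line = line[known_v & !pair_ok], issue = "unknown-recommendation-label")
    ))
  }
  problems <- bind_rows(issues) |> arrange(.data$line)
  keep <- !line %in% problems$line
  out <- raw[keep, ] |>
    mutate(round = as.integer(.data$round),
           estimate = as.numeric(.data$estimate))
  attr(out, "problems") <- problems
  out
}

#' Write per-trial edge lists
#'
#' @param topology A [regular_network()].
#' @param trial_ids Trial labels; the topology is emitted once per trial
#'   (network trials share one canonical topology).
#' @param path Output file with header `trial_id,node_a,node_b`.
#' @export
write_edges <- function(topology, trial_ids, path) {
  edges <- purrr::map(trial_ids, function(tid) {
    mutate(topology$edges, trial_id = tid, .before = 1)
  }) |> list_rbind()
  readr::write_csv(edges, path)
  invisible(path)
}

#' Read per-trial edge lists
#'
#' @param path File written by [write_edges()].
#' @return Tibble `trial_id`, `node_a`, `node_b`; the topology of one trial
#'   can be rebuilt with [edges_to_topology()].
#' @export
read_edges <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    trial_id = readr::col_character(),
                    node_a = readr::col_integer(),
                    node_b = readr::col_integer()
                  ))
}

#' Rebuild a topology object from an edge table
#'
#' @param edges Tibble with `node_a`, `node_b` for a single trial.
#' @return A [regular_network()] object.
#' @export
edges_to_topology <- function(edges) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  n <- length(nodes)
  deg <- tabulate(c(edges$node_a, edges$node_b) + 1L, nbins = n)
  lo <- pmin(edges$node_a, edges$node_b)
  hi <- pmax(edges$node_a, edges$node_b)
  ord <- order(lo, hi)
  new_regular_network(n, deg[1], tibble(node_a = lo[ord], node_b = hi[ord]))
}

# Study configuration ----------------------------------------------------

#' Assemble a study configuration
#'
#' Bundles everything needed to simulate and analyse a study: the vignette
#' definitions, trials per condition per vignette, generator parameters,
#' analysis options, and the master seed.
#'
#' @param vignettes Vignette table (default [default_vignettes()]).
#' @param trials_network,trials_control Trials per vignette per condition.
#' @param gen_config A [generator_config()].
#' @param n_clinicians,n_rounds Panel dimensions.
#' @param norm,binning Analysis options (see [run_analyze()]).
#' @param seed Master seed.
#' @return A `study_config` object.
#' @export
study_config <- function(vignettes = default_vignettes(),
                         trials_network = 8L, trials_control = 4L,
                         gen_config = generator_config(),
                         n_clinicians = 40L, n_rounds = 3L,
                         norm = "fixed", binning = "condition", seed = 1L) {
  vid <- vignettes$vignette_id
  if (anyDuplicated(vid)) {
    abort("every vignette must be defined exactly once.",
          class = "netwisdom_invalid_parameters")
  }
  structure(
    list(vignettes = vignettes, trials_network = as.integer(trials_network),
         trials_control = as.integer(trials_control), gen_config = gen_config,
         n_clinicians = as.integer(n_clinicians), n_rounds = as.integer(n_rounds),
         norm = norm, binning = binning, seed = as.integer(seed)),
    class = "study_config"
  )
}

config_to_list <- function(config) {
  list(
    vignettes = purrr::pmap(
      config$vignettes,
      function(vignette_id, truth, options, thresholds, correct_option) {
        list(vignette_id = vignette_id, truth = truth, options = options,
             thresholds = thresholds, correct_option = correct_option)
      }
    ),
    trials_network = config$trials_network,
    trials_control = config$trials_control,
    generator = unclass(config$gen_config),
    n_clinicians = config$n_clinicians,
    n_rounds = config$n_rounds,
    norm = config$norm,
    binning = config$binning,
    seed = config$seed
  )
}

#' Write a study configuration to YAML
#' @param config A [study_config()].
#' @param path Output file.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' Read a study configuration from YAML
#' @param path File written by [write_study_config()] (or hand-authored
#'   with the same keys).
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  vignettes <- purrr::map(y$vignettes, function(v) {
    tibble(vignette_id = v$vignette_id, truth = v$truth,
           options = list(unlist(v$options)),
           thresholds = list(unlist(v$thresholds)),
           correct_option = v$correct_option)
  }) |> list_rbind()
  study_config(
    vignettes = vignettes,
    trials_network = y$trials_network, trials_control = y$trials_control,
    gen_config = do.call(generator_config, y$generator),
    n_clinicians = y$n_clinicians, n_rounds = y$n_rounds,
    norm = y$norm %||% "fixed", binning = y$binning %||% "condition",
    seed = y$seed %||% 1L
  )
}

config_hash <- function(config) {
  fnv1a_hash(yaml::as.yaml(config_to_list(config)))
}

# Pipeline commands ------------------------------------------------------

#' Simulate a study and write its dataset files
#'
#' Generates a full synthetic study from a [study_config()] and writes
#' `responses.csv`, `edges.csv`, `trials.csv`, `config.yaml` and a
#' `manifest.json` provenance record (config hash, master seed, package
#' version) into `out_dir`.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override of `config$seed`.
#' @return The simulated `ci_study`, invisibly.
#' @export
run_simulate <- function(config, out_dir, seed = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    abort(sprintf("cannot create output directory '%s'.", out_dir),
          class = "netwisdom_io_error")
  }
  study <- simulate_study(
    vignettes = config$vignettes,
    trials_network = config$trials_network,
    trials_control = config$trials_control,
    gen_config = config$gen_config,
    n_clinicians = config$n_clinicians, n_rounds = config$n_rounds,
    seed = config$seed
  )
  write_responses(study$responses, file.path(out_dir, "responses.csv"))
  net_ids <- study$trials$trial_id[study$trials$condition == "network"]
  if (length(net_ids) > 0) {
    write_edges(study$topology, net_ids, file.path(out_dir, "edges.csv"))
  }
  readr::write_csv(study$trials, file.path(out_dir, "trials.csv"))
  write_study_config(config, file.path(out_dir, "config.yaml"))
  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package = "netwisdom",
    version = as.character(utils::packageVersion("netwisdom")),
    n_trials = nrow(study$trials),
    n_responses = nrow(study$responses)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(study)
}

#' Load a simulated dataset directory back into a study object
#'
#' @param data_dir Directory written by [run_simulate()].
#' @return A list with `responses`, `vignettes`, `trials`, `config`,
#'   usable by [run_analyze()].
#' @export
read_study <- function(data_dir) {
  config <- read_study_config(file.path(data_dir, "config.yaml"))
  responses <- read_responses(file.path(data_dir, "responses.csv"),
                              vignettes = config$vignettes)
  trials <- readr::read_csv(file.path(data_dir, "trials.csv"),
                            show_col_types = FALSE)
  list(responses = responses, vignettes = config$vignettes,
       trials = trials, config = config)
}

#' Write the analysis bundle to a results directory
#'
#' Serializes every table of a `ci_analysis` as delimited text plus a
#' provenance manifest, and renders the plain-text report.
#'
#' @param analysis A `ci_analysis`.
#' @param out_dir Output directory (created if needed).
#' @param config Optional [study_config()] recorded in the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(analysis, out_dir, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("overall", "trial_summaries", "quartile_contrasts",
              "quartile_table", "decile_revision", "switch_summary", "tests")
  for (tb in tables) {
    if (!is.null(analysis[[tb]])) {
      readr::write_csv(analysis[[tb]], file.path(out_dir, paste0(tb, ".csv")))
    }
  }
  run_report(analysis, file.path(out_dir, "report.txt"))
  manifest <- list(
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    analysis_seed = analysis$options$seed,
    options = analysis$options[c("norm", "binning", "jt_mode", "jt_n_perm")],
    package = "netwisdom",
    version = as.character(utils::packageVersion("netwisdom"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Reload a serialized analysis bundle
#'
#' Reconstructs a `ci_analysis` from the delimited tables and manifest that
#' [write_analysis()] wrote, e.g. to re-render its report.
#'
#' @param results_dir Directory written by [write_analysis()].
#' @return A `ci_analysis` object.
#' @export
read_analysis <- function(results_dir) {
  read_tbl <- function(name) {
    p <- file.path(results_dir, paste0(name, ".csv"))
    if (file.exists(p)) readr::read_csv(p, show_col_types = FALSE) else NULL
  }
  manifest <- jsonlite::read_json(file.path(results_dir, "manifest.json"))
  structure(
    list(
      overall = read_tbl("overall"),
      trial_summaries = read_tbl("trial_summaries"),
      quartile_contrasts = read_tbl("quartile_contrasts"),
      quartile_table = read_tbl("quartile_table"),
      decile_revision = read_tbl("decile_revision"),
      switch_summary = read_tbl("switch_summary"),
      tests = read_tbl("tests"),
      options = c(manifest$options, list(seed = manifest$analysis_seed)),
      exclusions = NULL
    ),
    class = "ci_analysis"
  )
}
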