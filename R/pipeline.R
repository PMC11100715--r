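#' Default pipeline configuration
#'
#' All tunables of the simulation-to-hypothesis workflow in one list:
#' ground-truth size, knockout-screen options, classifier choice and
#' hyperparameter overrides, patient-pair noise, and output directory. The
#' resolved configuration is written beside every run's outputs so a run can
#' be reproduced from its own records.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    outdir = "stateshift_run",
    n_nodes = 24,
    n_states = 4,
    classifier = "boosted_trees",
    augment_copies = 0,
    augment_rate = 0.05,
    n_pairs = 20,
    flip_rate = 0.05,
    max_path_len = 4)
  override <- list(...)
  bad <- setdiff(names(override), names(cfg))
  if (length(bad)) stop_ctx("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg[names(override)] <- override
  cfg
}

#' Run the simulation-to-prediction workflow end to end
#'
#' Stages, in dependency order: generate a ground-truth model and planted
#' profiles; write its network and rules; re-synthesize rules from the
#' derived network as a consistency check; run the knockout screen; train the
#' configured classifier on the screen; simulate paired primary/recurrent
#' profiles and predict their states. Every output is a deterministic
#' plain-text file; a JSON manifest records input hashes, seeds, package
#' version and per-stage row counts, and the resolved configuration is
#' written as YAML beside the outputs.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file of overrides.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_ctx("config file not found: %s", config)
    config <- do.call(default_config, yaml::read_yaml(config))
  }
  stopifnot(is.list(config))
  cfg <- do.call(default_config, config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  counts <- list()

  # stage: generate
  gt <- generate_ground_truth_model(cfg$n_nodes, cfg$n_states, seed = cfg$seed)
  write_signed_network(gt$network, out("network.tsv"))
  write_rules(gt$model, out("rules.txt"))
  profile_mat <- do.call(rbind, gt$profiles)
  write_matrix_tsv(t(profile_mat), out("profiles.tsv"), id_col = "node")
  counts$generate <- list(nodes = length(gt$model$nodes),
                          states = length(gt$profiles))

  # stage: synthesize (consistency check against the derived network)
  syn <- synthesize_rules(gt$network, gt$profiles)
  utils::write.table(syn$report, out("synthesis_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts$synthesize <- list(nodes = nrow(syn$report),
                            infeasible = sum(!syn$report$feasible))

  # stage: screen
  screen <- knockout_screen(syn$model, gt$profiles)
  write_screen_tsv(screen, out("ko_screen.tsv"), out("ko_screen_long.tsv"))
  counts$screen <- list(simulations = nrow(screen$table))

  # stage: train
  ts <- build_training_set(screen)
  clf <- train_classifier(ts, model_spec(cfg$classifier, seed = cfg$seed),
                          augment_rate = cfg$augment_rate,
                          augment_copies = cfg$augment_copies)
  counts$train <- list(rows = nrow(ts$X), classes = length(clf$classes))

  # stage: predict on simulated patient pairs
  pred_rows <- list()
  for (i in seq_len(cfg$n_pairs)) {
    sts <- sample_pair_states(gt$states, cfg$seed + i)
    pair <- generate_patient_pair(gt$profiles, sts[1], sts[2],
                                  cfg$flip_rate, seed = cfg$seed + i)
    pp <- predict_state(clf, rbind(primary = pair$primary,
                                   recurrent = pair$recurrent))
    pred_rows[[i]] <- data.frame(
      pair = i, member = pp$sample, planted = c(sts[1], sts[2]),
      predicted = pp$state, stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, pred_rows)
  utils::write.table(predictions, out("pair_predictions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts$predict <- list(pairs = cfg$n_pairs,
                         accuracy = mean(predictions$planted == predictions$predicted))

  yaml::write_yaml(cfg, out("config.yaml"))
  outputs <- c("network.tsv", "rules.txt", "profiles.tsv",
               "synthesis_report.tsv", "ko_screen.tsv", "ko_screen_long.tsv",
               "pair_predictions.tsv", "config.yaml")
  manifest <- list(
    package = "stateshift",
    version = as.character(utils::packageVersion("stateshift")),
    seed = cfg$seed,
    stage_counts = counts,
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(cfg$outdir, outputs))), outputs)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(ground_truth = gt, synthesis = syn, screen = screen,
                 classifier = clf, predictions = predictions,
                 manifest = manifest, config = cfg))
}

# deterministic ordered pair of distinct states for pair i
sample_pair_states <- function(states, seed) {
  local_seed(seed, sample(states, 2))
}
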