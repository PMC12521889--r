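# Session container I/O and experiment orchestration.
#
# A session is stored as a plain-text directory bundle: `meta.json`
# (config, stimulus set, ground-truth latents, schema version),
# `behavior.csv` (the canonical behavior table) and `spikes.csv`
# (trials x (cells*bins) integer matrix, cells varying fastest).  The
# bundle round-trips bit-exactly.  No binary/HDF5 dependency exists in
# this stack; the schema mirrors the usual layout (one dataset per
# tensor plus JSON attributes) in text form.

SESSION_SCHEMA <- 1L

#' Write a session to a plain-text bundle
#'
#' @param session a `session_data`.
#' @param path directory to create (overwritten if existing).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_data"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(session$spikes)
  meta <- list(schema = SESSION_SCHEMA,
               dims = d,
               bin_width = session$config$bin_width,
               window_start = session$config$window_start,
               seed = session$config$seed,
               config = unclass(session$config),
               stimulus_set = unclass(session$stimulus_set),
               latent = session$latent)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(session$behavior, file.path(path, "behavior.csv"),
            row.names = FALSE)
  write.csv(matrix(as.integer(session$spikes), d[1]),
            file.path(path, "spikes.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a session bundle
#'
#' @param path directory written by [write_session()].
#' @return a `session_data`; malformed bundles raise schema errors naming
#'   the offending field.
#' @export
read_session <- function(path) {
  meta_f <- file.path(path, "meta.json")
  if (!file.exists(meta_f)) stop("schema error: missing meta.json")
  meta <- jsonlite::read_json(meta_f, simplifyVector = TRUE)
  if (is.null(meta$schema) || meta$schema > SESSION_SCHEMA)
    stop("schema error: unsupported schema version")
  behavior <- read.csv(file.path(path, "behavior.csv"))
  needed <- c("trial", "stim_first", "stim_second", "value_first",
              "value_second", "choice")
  missing <- setdiff(needed, names(behavior))
  if (length(missing))
    stop("schema error: behavior table missing column(s): ",
         paste(missing, collapse = ", "))
  sp <- as.matrix(read.csv(file.path(path, "spikes.csv")))
  d <- as.integer(meta$dims)
  if (!identical(dim(sp), c(d[1], d[2] * d[3])))
    stop("schema error: spikes shape mismatch")
  spikes <- array(as.integer(sp), d)
  cfg <- meta$config
  config <- do.call(simulator_config, cfg[setdiff(names(cfg), "")])
  stim <- structure(list(items = as.integer(meta$stimulus_set$items),
                         value_level = as.integer(meta$stimulus_set$value_level)),
                    class = "stimulus_set")
  lat <- meta$latent
  if (!is.null(lat$subjective)) lat$subjective <- as.matrix(lat$subjective)
  structure(list(spikes = spikes, behavior = behavior,
                 stimulus_set = stim, config = config, latent = lat),
            class = "session_data")
}

#' Export the behavior table to CSV
#'
#' Header: `trial,stim_first,stim_second,value_first,value_second,choice`.
#' @param session a `session_data`.
#' @param file output path.
#' @export
write_behavior_csv <- function(session, file) {
  write.csv(session$behavior, file, row.names = FALSE)
  invisible(file)
}

#' Serialize scaler statistics to JSON (and back)
#'
#' @param stats the `stats` element of [fit_apply_scaler()].
#' @param file output path.
#' @export
scaler_to_json <- function(stats, file) {
  jsonlite::write_json(lapply(stats, function(m)
    list(dim = dim(m), values = as.vector(m))), file,
    auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname scaler_to_json
#' @export
scaler_from_json <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  lapply(raw, function(e) array(e$values, e$dim))
}

#' Save / load a trained agent
#'
#' Checkpoints are runtime artifacts (R serialization); they carry every
#' named parameter tensor plus the architecture configuration, and
#' round-trip exactly.
#'
#' @param agent a trained agent (any of the agent classes).
#' @param path file path.
#' @export
save_agent <- function(agent, path) {
  saveRDS(agent, path)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) readRDS(path)

#' Default experiment configuration
#'
#' Every stochastic component derives its seed from `seed`; rerunning the
#' same configuration reproduces every output bit-for-bit.
#'
#' @param seed master seed.
#' @param ... overrides for the `simulator`, `preprocess`, `env`, `model`,
#'   `train`, `analyze` and `benchmark` sections (named lists, merged over
#'   the defaults).
#' @export
experiment_config <- function(seed = 1, ...) {
  base <- list(
    seed = seed,
    simulator = list(n_trials = 600, n_cells = 27),
    preprocess = list(train_fraction = 0.8,
                      augment = list(enabled = TRUE, noise_bound = 0.1,
                                     multiplier = 1, mode = "fixed")),
    env = list(type = "env1", mode = "order", episode_length = 128,
               cutoff = "uniform"),
    model = list(d_model = 100, n_heads = 4, d_ff = 200, n_layers = 2),
    train = list(n_iterations = 100, n_episodes = 5, batch_size = 256,
                 lr = 1e-3, steps_per_iter = 1),
    analyze = list(representation_decoding = FALSE,
                   value_difference = TRUE),
    benchmark = list(baselines = FALSE, uncertainty = FALSE)
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (is.list(ov[[nm]]) && is.list(base[[nm]]))
      base[[nm]][names(ov[[nm]])] <- ov[[nm]]
    else base[[nm]] <- ov[[nm]]
  }
  base
}

#' Read an experiment configuration from JSON
#' @param path JSON file with any subset of the configuration sections.
#' @export
read_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config,
          c(list(seed = raw$seed %||% 1),
            raw[setdiff(names(raw), "seed")]))
}

#' Run a full experiment from a configuration
#'
#' simulate -> preprocess -> train -> evaluate (+ optional analyses), with
#' all outputs written as CSV/JSON under `out_dir` and headline metrics in
#' `summary.json`.
#'
#' @param config an [experiment_config()] (or path to a JSON config).
#' @param out_dir output directory.
#' @return the summary list, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- read_experiment_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    sim_args <- config$simulator
    sim_args$seed <- derive_seed(config$seed, "sim")
    cfg <- do.call(simulator_config, sim_args)
    session <- generate_session(cfg)
    write_session(session, file.path(out_dir, "session"))

    stage <- "preprocess"
    split <- split_trials(cfg$n_trials, config$preprocess$train_fraction,
                          seed = derive_seed(config$seed, "split"))
    sc <- fit_apply_scaler(session, split)
    scaler_to_json(sc$stats, file.path(out_dir, "scaler.json"))
    Xa <- aperm(sc$scaled, c(2, 3, 1))
    pool_idx <- split$train
    feats <- Xa[, , split$train, drop = FALSE]
    pool_choice <- session$behavior$choice[split$train]
    if (isTRUE(config$preprocess$augment$enabled)) {
      aug <- augment_trials(sc$scaled[split$train, , , drop = FALSE],
                            config$preprocess$augment$noise_bound,
                            config$preprocess$augment$multiplier,
                            seed = derive_seed(config$seed, "augment"))
      feats <- array(c(feats, aperm(aug$x, c(2, 3, 1))),
                     c(dim(Xa)[1], dim(Xa)[2], dim(feats)[3] + dim(aug$x)[1]))
      pool_idx <- c(split$train, split$train[aug$source])
      pool_choice <- c(pool_choice, session$behavior$choice[
        split$train[aug$source]])
    }

    stage <- "train"
    tc <- do.call(train_config, c(config$train,
                                  list(seed = derive_seed(config$seed, "rl"))))
    env <- env_choice(feats, pool_choice,
                      episode_length = config$env$episode_length,
                      seed = derive_seed(config$seed, "env"))
    if (isTRUE(config$preprocess$augment$enabled) &&
        identical(config$preprocess$augment$mode, "per_episode")) {
      n_real <- length(split$train)
      base <- aperm(sc$scaled[split$train[aug$source], , , drop = FALSE],
                    c(2, 3, 1))
      set_per_episode_augmentation(env, (n_real + 1):dim(feats)[3], base,
                                   config$preprocess$augment$noise_bound)
    }
    agent <- do.call(core_agent, c(list(n_cells = cfg$n_cells,
                                        n_bins = cfg$n_bins,
                                        seed = derive_seed(config$seed, "agent")),
                                   config$model))
    tr <- train_agent(env, agent, tc)
    write.csv(tr$log, file.path(out_dir, "training_log.csv"),
              row.names = FALSE)

    stage <- "evaluate"
    ev <- evaluate_agent(tr$agent, Xa[, , split$test, drop = FALSE],
                         session$behavior$choice[split$test])
    summary <- list(seed = config$seed,
                    n_trials = cfg$n_trials, n_cells = cfg$n_cells,
                    train_accuracy = utils::tail(tr$log$train_accuracy, 1),
                    held_out_accuracy = ev$accuracy)
    if (isTRUE(config$analyze$value_difference)) {
      avd <- accuracy_by_value_difference(
        session$behavior[split$test, ], ev$predicted)
      write.csv(avd, file.path(out_dir, "accuracy_by_delta.csv"),
                row.names = FALSE)
      summary$delta0_accuracy <- avd$accuracy[avd$delta == 0]
    }
    if (isTRUE(config$analyze$representation_decoding)) {
      rd <- decode_values_from_representations(tr$agent, sc$scaled,
                                               session$behavior, split)
      write.csv(rd, file.path(out_dir, "representation_decoding.csv"),
                row.names = FALSE)
      summary$representation_r2 <- as.list(stats::setNames(rd$r2, rd$target))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    summary
  }, error = function(e) {
    stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
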