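# High-level experiment drivers.  These freeze the desk-scale protocols
# used by the acceptance suite and the acceptance script, so that both
# always run the identical procedure.

#' Choice-decoding experiment (full-trial environment)
#'
#' For each synthetic session: generate with frozen defaults, split
#' train/test, scale, augment the training trials once (uniform noise
#' 0.1), train the transformer Q-decoder with the offline RL loop, and
#' evaluate held-out accuracy.
#'
#' @param seed master seed; every per-session seed derives from it.
#' @param n_sessions number of independent sessions.
#' @param n_iterations RL iterations (100 = desk scale; 300 = full scale).
#' @param train_fraction training fraction.
#' @param compute_oracle also run the likelihood-ratio oracle per session.
#' @param keep_objects keep per-session agents/sessions/splits for further
#'   analysis (memory permitting).
#' @return list: `results` (one row per session: `held_out_accuracy`,
#'   `train_accuracy`, `oracle`), `mean_accuracy`, and (optionally)
#'   `objects`.
#' @export
run_choice_decoding_experiment <- function(seed = 1, n_sessions = 5,
                                           n_iterations = 100,
                                           train_fraction = 0.8,
                                           compute_oracle = FALSE,
                                           keep_objects = FALSE) {
  rows <- vector("list", n_sessions)
  objs <- vector("list", n_sessions)
  for (k in seq_len(n_sessions)) {
    sk <- derive_seed(seed, "t4", k)
    s <- generate_session(simulator_config(seed = derive_seed(sk, "sess")))
    split <- split_trials(s$config$n_trials, train_fraction,
                          seed = derive_seed(sk, "split"))
    sc <- fit_apply_scaler(s, split)
    Xa <- aperm(sc$scaled, c(2, 3, 1))
    aug <- augment_trials(sc$scaled[split$train, , , drop = FALSE],
                          seed = derive_seed(sk, "aug"))
    n_tr <- length(split$train)
    feats <- array(c(Xa[, , split$train], aperm(aug$x, c(2, 3, 1))),
                   c(dim(Xa)[1], dim(Xa)[2], n_tr + dim(aug$x)[1]))
    pool <- c(split$train, split$train[aug$source])
    env <- env_choice(feats, s$behavior$choice[pool],
                      episode_length = 128, seed = derive_seed(sk, "env"))
    agent <- core_agent(s$config$n_cells, s$config$n_bins,
                        seed = derive_seed(sk, "agent"))
    tr <- train_agent(env, agent,
                      train_config(n_iterations = n_iterations,
                                   seed = derive_seed(sk, "rl")))
    ev <- evaluate_agent(tr$agent, Xa[, , split$test, drop = FALSE],
                         s$behavior$choice[split$test])
    orc <- if (compute_oracle) bayes_oracle_accuracy(s)$accuracy else NA_real_
    rows[[k]] <- data.frame(session = k,
                            held_out_accuracy = ev$accuracy,
                            train_accuracy =
                              utils::tail(tr$log$train_accuracy, 1),
                            oracle = orc)
    if (keep_objects)
      objs[[k]] <- list(session = s, split = split, scaled = sc,
                        agent = tr$agent, log = tr$log, eval = ev)
  }
  results <- do.call(rbind, rows)
  out <- list(results = results,
              mean_accuracy = mean(results$held_out_accuracy))
  if (keep_objects) out$objects <- objs
  out
}

#' Early-prediction experiment (masked environment, forecasting agents)
#'
#' Per session: train the stimulus-conditioned forecaster on the training
#' split, then a BASE agent (core decoder, uniform random cutoffs) and a
#' STIM agent (combined core + forecasting paths) in the masked
#' environment; compute held-out accuracy versus cutoff; define the
#' criterion as the midpoint between chance and the BASE agent's
#' full-cutoff accuracy, and report the lead time (ms) by which the STIM
#' agent reaches criterion at an earlier real-data cutoff.
#'
#' Desk-scale iteration counts (BASE 120, STIM 60, forecaster 120 epochs)
#' are frozen here; see the methods vignette.
#'
#' @param seed master seed.
#' @param n_sessions number of sessions.
#' @param base_iters,stim_iters,fc_epochs training budgets.
#' @return list: `per_session` (curves, criterion, crossing times, lead),
#'   `leads_ms`, `mean_lead_ms`.
#' @export
run_early_prediction_experiment <- function(seed = 1, n_sessions = 5,
                                            base_iters = 120,
                                            stim_iters = 60,
                                            fc_epochs = 120) {
  per <- vector("list", n_sessions)
  for (k in seq_len(n_sessions)) {
    sk <- derive_seed(seed, "t5", k)
    s <- generate_session(simulator_config(seed = derive_seed(sk, "sess")))
    split <- split_trials(s$config$n_trials, 0.8,
                          seed = derive_seed(sk, "split"))
    sc <- fit_apply_scaler(s, split)
    Xa <- aperm(sc$scaled, c(2, 3, 1))
    tags <- stimulus_tags(s$stimulus_set, seed = derive_seed(sk, "tags"))
    tin <- tag_inputs(s$behavior, tags, s$config)
    fc <- train_forecaster(sc$scaled, split,
                           srnn_init(s$config$n_cells,
                                     seed = derive_seed(sk, "fc")),
                           tin, epochs = fc_epochs, batch_size = 64,
                           lr = 2e-3, seed = derive_seed(sk, "fctrain"))
    aug <- augment_trials(sc$scaled[split$train, , , drop = FALSE],
                          seed = derive_seed(sk, "aug"))
    feats <- array(c(Xa[, , split$train], aperm(aug$x, c(2, 3, 1))),
                   c(dim(Xa)[1], dim(Xa)[2],
                     length(split$train) + dim(aug$x)[1]))
    pool <- c(split$train, split$train[aug$source])
    pc <- s$behavior$choice[pool]
    mk_env <- function(tag) env_masked(feats, pc,
                                       s$behavior$stim_first[pool],
                                       s$behavior$stim_second[pool],
                                       episode_length = 64,
                                       seed = derive_seed(sk, "env", tag))
    base_tr <- train_agent(mk_env("B"),
                           core_agent(s$config$n_cells, s$config$n_bins,
                                      seed = derive_seed(sk, "agB")),
                           train_config(n_iterations = base_iters,
                                        steps_per_iter = 2,
                                        batch_size = 192,
                                        seed = derive_seed(sk, "rlB")))
    stim_ag <- combined_agent(s$config$n_cells, s$config$n_bins,
                              fc$forecaster, tags,
                              seed = derive_seed(sk, "agS"))
    stim_tr <- train_agent(mk_env("S"), stim_ag,
                           train_config(n_iterations = stim_iters,
                                        steps_per_iter = 2,
                                        batch_size = 192,
                                        seed = derive_seed(sk, "rlS")),
                           tags_in = tin[, , pool, drop = FALSE])
    curves <- ablation_cutoff_curves(
      list(BASE = base_tr$agent, STIM = stim_tr$agent),
      Xa[, , split$test, drop = FALSE], s$behavior$choice[split$test],
      tin[, , split$test, drop = FALSE],
      cases = c("BASE", "STIM"))      # ablation cases not needed for the lead
    bfull <- curves$accuracy[curves$case == "BASE" &
                               curves$cutoff == s$config$n_bins]
    crit <- (0.5 + bfull) / 2
    cb <- criterion_crossing_time(curves[curves$case == "BASE", ], crit,
                                  s$config)
    cs <- criterion_crossing_time(curves[curves$case == "STIM", ], crit,
                                  s$config)
    per[[k]] <- list(curves = curves, criterion = crit,
                     base_crossing_s = cb, stim_crossing_s = cs,
                     lead_ms = 1000 * (cb - cs),
                     forecaster_frozen =
                       isTRUE(stim_tr$forecaster_checksum[1] ==
                                stim_tr$forecaster_checksum[2]))
  }
  leads <- vapply(per, function(p) p$lead_ms, 0)
  list(per_session = per, leads_ms = leads,
       mean_lead_ms = mean(leads, na.rm = TRUE))
}
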