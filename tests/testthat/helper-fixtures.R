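# Shared fixtures, memoised per test run.  Everything is generated in code
# at test time; nothing is read from disk.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# a small but realistic session: 200 trials x 12 cells, frozen kernels
small_session <- function() memo("small_session", {
  generate_session(simulator_config(n_trials = 200, n_cells = 12, seed = 7))
})

small_scaled <- function() memo("small_scaled", {
  s <- small_session()
  split <- split_trials(200, 0.75, seed = 11)
  sc <- fit_apply_scaler(s, split)
  list(session = s, split = split, scaled = sc$scaled, stats = sc$stats,
       Xa = aperm(sc$scaled, c(2, 3, 1)))
})

# acceptance-scale experiments (shared between the acceptance file and
# module tests that interrogate fully trained agents)
t4_run <- function() memo("t4_run", {
  run_choice_decoding_experiment(seed = 1, n_sessions = 3,
                                 n_iterations = 100,
                                 compute_oracle = TRUE,
                                 keep_objects = TRUE)
})

t5_run <- function() memo("t5_run", {
  run_early_prediction_experiment(seed = 1, n_sessions = 2)
})

# an Env-1-trained agent on the small session (40 iterations)
trained_small_agent <- function() memo("trained_small_agent", {
  sc <- small_scaled()
  tr <- sc$split$train
  env <- env_choice(sc$Xa[, , tr, drop = FALSE],
                    sc$session$behavior$choice[tr],
                    episode_length = 64, seed = 41)
  train_agent(env, core_agent(12, 12, seed = 42),
              train_config(n_iterations = 40, batch_size = 128,
                           seed = 43))$agent
})

# tiny transformer dimensions for gradient checks
tiny_tf <- function(seed = 3) tf_init(3, d_model = 8, n_heads = 2,
                                      d_ff = 12, n_layers = 2, seed = seed)

# central finite difference for a scalar-valued function of a parameter list
fd_check <- function(loss_fn, params, grads, n_per = 4, eps = 1e-5,
                     keep_attrs = attributes(params)) {
  worst <- 0
  for (nm in names(params)) {
    for (i in seq_len(min(n_per, length(params[[nm]])))) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      attributes(pp) <- keep_attrs
      f1 <- loss_fn(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
      f0 <- loss_fn(pp)
      num <- (f1 - f0) / (2 * eps)
      worst <- max(worst, abs(num - grads[[nm]][i]) /
                     max(1, abs(num) + abs(grads[[nm]][i])))
    }
  }
  worst
}
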