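# Offline RL training.
#
# The loop follows the standard offline scheme: on each iteration the
# agent runs N_E episodes under a Boltzmann policy, appends the observed
# (s, s', r, a) tuples to a FIFO replay buffer, samples K tuples uniformly
# and takes `steps_per_iter` Adam steps on the mean-squared error between
# Q(s, a) and the Q-learning target r + g max_a' Q(s', a').  The choice
# environments use g = 0 (single-prediction trials are terminal), the
# sequence environment g = 0.99 with a softly-updated target network.

#' Q-learning target value
#'
#' `r + g * max_a' Q(s', a')`; a terminal transition contributes no future
#' term regardless of `g`.
#'
#' @param r reward.
#' @param q_next Q values at the next state (vector), or `NULL` if
#'   terminal.
#' @param g discount factor in `[0, 1]`.
#' @param terminal logical; defaults to `TRUE` when `q_next` is `NULL`.
#' @return scalar target.
#' @export
q_target <- function(r, q_next = NULL, g = 0, terminal = is.null(q_next)) {
  if (terminal || g == 0) return(r)
  r + g * max(q_next)
}

#' Soft (Polyak) target-network update
#'
#' `theta_target <- rho * theta_online + (1 - rho) * theta_target`,
#' elementwise over conformable parameter lists.
#'
#' @param target,online named parameter lists.
#' @param rho mixing rate in `[0, 1]` (1 = hard copy).
#' @export
soft_update <- function(target, online, rho = 0.005) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  for (nm in names(target)) {
    if (!identical(dim(target[[nm]]), dim(online[[nm]])) ||
        length(target[[nm]]) != length(online[[nm]]))
      stop("shape mismatch in soft_update: ", nm)
    target[[nm]] <- rho * online[[nm]] + (1 - rho) * target[[nm]]
  }
  target
}

#' Replay buffer (FIFO, uniform sampling)
#'
#' Transitions are stored as rows of a numeric matrix; columns are
#' interpreted by the trainer.  Sampling of `K` rows is uniform without
#' replacement whenever the buffer holds at least `K`.
#'
#' @param capacity maximum rows retained (oldest evicted first).
#' @param n_cols columns per transition record.
#' @export
replay_buffer <- function(capacity = 50000, n_cols = 5) {
  b <- new.env(parent = emptyenv())
  b$data <- matrix(NA_real_, 0, n_cols)
  b$capacity <- capacity
  b$add <- function(rows) {
    b$data <- rbind(b$data, rows)
    n <- nrow(b$data)
    if (n > b$capacity) b$data <- b$data[(n - b$capacity + 1):n, , drop = FALSE]
    invisible(NULL)
  }
  b$size <- function() nrow(b$data)
  b$sample <- function(k) {
    n <- nrow(b$data)
    if (n == 0) return(NULL)
    idx <- if (n >= k) sample(n, k) else sample(n, k, replace = TRUE)
    b$data[idx, , drop = FALSE]
  }
  class(b) <- c("replay_buffer", "environment")
  b
}

#' Training configuration for the RL loop
#'
#' @param n_iterations Algorithm iterations N_I (300 for the choice
#'   environments at full scale).
#' @param n_episodes episodes per iteration N_E (5).
#' @param batch_size replay sample size K.
#' @param discount discount factor g (0 for the choice environments, 0.99
#'   for the sequence environment).
#' @param tau Boltzmann temperature.
#' @param lr Adam learning rate.
#' @param steps_per_iter gradient steps per iteration.
#' @param rho soft-update rate for the target network.
#' @param buffer_capacity replay capacity.
#' @param cql_weight conservative regularizer weight (value-mapped
#'   sequence task; 0 disables).
#' @param seed master seed for rollout/sampling randomness.
#' @export
train_config <- function(n_iterations = 300, n_episodes = 5,
                         batch_size = 256, discount = 0, tau = 1,
                         lr = 1e-3, steps_per_iter = 1, rho = 0.005,
                         buffer_capacity = 50000, cql_weight = 0,
                         seed = 1) {
  stopifnot(discount >= 0, discount <= 1)
  as.list(environment())
}

# assemble forecast batch for a combined agent from a per-cutoff cache
fc_batch <- function(fc_cache, pool_idx, cutoffs) {
  d <- dim(fc_cache[[1]])
  out <- array(0, c(d[1], d[2], length(pool_idx)))
  for (ct in unique(cutoffs)) {
    sel <- which(cutoffs == ct)
    out[, , sel] <- fc_cache[[ct]][, , pool_idx[sel], drop = FALSE]
  }
  out
}

agent_q <- function(agent, X, cutoffs = NULL, fc_cache = NULL,
                    pool_idx = NULL, keep_state = FALSE) {
  Tb <- dim(as_trial_array(X))[2]
  if (inherits(agent, "combined_agent")) {
    fc <- fc_batch(fc_cache, pool_idx, cutoffs)
    combined_forward(agent, X, cutoffs, fc, keep_state = keep_state)
  } else {
    mask <- if (is.null(cutoffs)) NULL else
      t(vapply(cutoffs, function(ct) as.integer(seq_len(Tb) <= ct),
               integer(Tb)))
    core_forward(agent, X, mask, keep_state = keep_state)
  }
}

#' Train a Q-decoding agent in a choice environment
#'
#' Runs the offline RL loop in [env_choice()] or [env_masked()].  For a
#' `combined_agent` the frozen forecaster's predictions are precomputed per
#' cutoff (`mean` mode) and routed through the forecasting path.
#'
#' @param env training environment.
#' @param agent a `core_agent` or `combined_agent`.
#' @param config a [train_config()].
#' @param tags_in tag inputs for the environment's trial pool (combined
#'   agents only; zeros for NOSTIM).
#' @return list: `agent` (trained), `log` (per-iteration data frame with
#'   `iteration`, `loss`, `train_accuracy`, `buffer_size`),
#'   `forecaster_checksum` (before/after, combined agents).
#' @export
train_agent <- function(env, agent, config = train_config(),
                        tags_in = NULL) {
  combined <- inherits(agent, "combined_agent")
  masked <- identical(env$kind, "env3")
  feats <- env$features
  Tb <- env$n_bins
  fc_cache <- NULL
  ck_before <- NA_real_
  if (combined) {
    if (is.null(tags_in)) stop("combined agents need tags_in")
    ck_before <- params_checksum(agent$forecaster)
    fc_cache <- lapply(seq_len(Tb), function(ct)
      forecast_fill(agent$forecaster, feats, tags_in, ct, "forecast"))
    # standardize the forecast path input with training-pool statistics
    agent$fc_stats <- lapply(fc_cache, forecast_stats)
    fc_cache <- lapply(seq_len(Tb), function(ct)
      forecast_standardize(fc_cache[[ct]], agent$fc_stats[[ct]]))
  }
  # optimizer state per trainable component (forecaster excluded: frozen)
  comp <- if (combined) c("tf_core", "tf_fore", "fusion") else c("tf", "head")
  opt <- lapply(comp, function(nm) adam_init(agent[[nm]]))
  names(opt) <- comp
  buf <- replay_buffer(config$buffer_capacity, n_cols = 4)
  log <- data.frame(iteration = integer(), loss = numeric(),
                    train_accuracy = numeric(), buffer_size = integer())
  if (config$n_iterations < 1)
    return(list(agent = agent, log = log,
                forecaster_checksum = c(ck_before, ck_before)))
  for (it in seq_len(config$n_iterations)) {
    acc_n <- acc_c <- 0
    for (ep in seq_len(config$n_episodes)) {
      env$reset()
      idx <- env$order
      cts <- if (masked) env$cutoffs else rep(Tb, length(idx))
      fw <- agent_q(agent, feats[, , idx, drop = FALSE],
                    if (masked || combined) cts else NULL,
                    fc_cache, idx)
      pr <- boltzmann_policy(fw$q, config$tau)
      a <- with_seed(derive_seed(config$seed, "act", it, ep),
                     sample_actions(pr))
      r <- as.numeric(a == env$choice[idx])
      greedy <- max.col(fw$q, ties.method = "first")
      acc_c <- acc_c + sum(greedy == env$choice[idx]); acc_n <- acc_n + length(idx)
      buf$add(cbind(idx, a, r, cts))
    }
    loss_it <- NA_real_
    for (st in seq_len(config$steps_per_iter)) {
      batch <- with_seed(derive_seed(config$seed, "sample", it, st),
                         buf$sample(config$batch_size))
      if (is.null(batch)) { warning("empty replay buffer; skipping update"); next }
      bidx <- batch[, 1]; ba <- batch[, 2]; br <- batch[, 3]; bct <- batch[, 4]
      fw <- agent_q(agent, feats[, , bidx, drop = FALSE],
                    if (masked || combined) bct else NULL, fc_cache, bidx,
                    keep_state = TRUE)
      K <- nrow(batch)
      sel <- cbind(seq_len(K), ba)
      tgt <- br                      # g = 0: one prediction per trial
      err <- fw$q[sel] - tgt
      loss_it <- mean(err^2)
      dq <- matrix(0, K, ncol(fw$q))
      dq[sel] <- 2 * err / K
      if (combined) {
        fc <- fc_batch(fc_cache, bidx, bct)
        gr <- combined_backward(agent, feats[, , bidx, drop = FALSE], fc, fw, dq)
      } else {
        mask <- if (masked) t(vapply(bct, function(ct)
          as.integer(seq_len(Tb) <= ct), integer(Tb))) else NULL
        gb <- core_backward(agent, feats[, , bidx, drop = FALSE], dq, mask,
                            fw = fw)
        gr <- list(tf = gb$tf, head = gb$head)
      }
      for (nm in comp) {
        up <- adam_step(agent[[nm]], gr[[nm]], opt[[nm]], lr = config$lr)
        cfg_attr <- attributes(agent[[nm]])
        agent[[nm]] <- up$params
        attributes(agent[[nm]]) <- cfg_attr
        opt[[nm]] <- up$state
      }
    }
    log <- rbind(log, data.frame(iteration = it, loss = loss_it,
                                 train_accuracy = acc_c / acc_n,
                                 buffer_size = buf$size()))
  }
  list(agent = agent, log = log,
       forecaster_checksum = c(ck_before,
                               if (combined) params_checksum(agent$forecaster)
                               else NA_real_))
}

#' Evaluate choice-prediction accuracy
#'
#' @param agent trained agent.
#' @param X `[cells x bins x trials]` scaled trials.
#' @param choice recorded choices (1/2).
#' @param cutoffs optional per-trial (or scalar) cutoffs; `NULL` = full.
#' @param tags_in tag inputs (combined agents).
#' @param ablation passed to [combined_forward()].
#' @param zero_tags replace tags by zeros at test time (the `no_stimvec`
#'   ablation).
#' @return list: `accuracy`, `predicted`, `q`, `p` (Boltzmann
#'   probabilities, used as the decoder's prediction scores).
#' @export
evaluate_agent <- function(agent, X, choice, cutoffs = NULL, tags_in = NULL,
                           ablation = "none", zero_tags = FALSE) {
  X <- as_trial_array(X)
  B <- dim(X)[3]; Tb <- dim(X)[2]
  if (inherits(agent, "combined_agent")) {
    cutoffs <- rep_len(cutoffs %||% Tb, B)
    if (zero_tags) tags_in <- tags_in * 0
    fc <- array(0, dim(X))
    for (ct in unique(cutoffs)) {
      sel <- which(cutoffs == ct)
      ffs <- forecast_fill(agent$forecaster, X[, , sel, drop = FALSE],
                           tags_in[, , sel, drop = FALSE], ct, "forecast")
      if (!is.null(agent$fc_stats))
        ffs <- forecast_standardize(ffs, agent$fc_stats[[ct]])
      fc[, , sel] <- ffs
    }
    fw <- combined_forward(agent, X, cutoffs, fc, ablation = ablation)
  } else {
    mask <- if (is.null(cutoffs)) NULL else
      t(vapply(rep_len(cutoffs, B), function(ct)
        as.integer(seq_len(Tb) <= ct), integer(Tb)))
    fw <- core_forward(agent, X, mask)
  }
  pred <- max.col(fw$q, ties.method = "first")
  list(accuracy = mean(pred == choice), predicted = pred, q = fw$q,
       p = boltzmann_policy(fw$q), chi = fw$chi %||% fw$chi_core)
}

#' Train the neural forecaster on the training split
#'
#' Teacher-forced minibatch Adam on the negative per-step ELBO.  Only
#' training trials may be passed; supplying held-out trials is a contract
#' violation and raises an error.
#'
#' @param scaled `[trials x cells x bins]` scaled session (all trials) or
#'   `[cells x bins x trials]` feature array.
#' @param split a `split_spec`; fitting uses `split$train` only.
#' @param forecaster an [srnn_init()] parameter set.
#' @param tags_in tag inputs for *all* trials (`tag_dim x bins x trials`),
#'   or `NULL` for NOSTIM (zero tags).
#' @param epochs,lr,batch_size optimization settings.
#' @param trials trials to fit on; must be a subset of `split$train`.
#' @param seed RNG seed (noise draws and batch order).
#' @return list: `forecaster` (trained), `log` (per-epoch mean loss).
#' @export
train_forecaster <- function(scaled, split, forecaster, tags_in = NULL,
                             epochs = 60, lr = 2e-3, batch_size = 128,
                             trials = NULL, seed = 1) {
  # canonical input: trials x cells x bins -> cells x bins x trials
  X <- aperm(scaled, c(2, 3, 1))
  trials <- trials %||% split$train
  if (length(setdiff(trials, split$train)) > 0)
    stop("contract violation: held-out trials passed to train_forecaster")
  X <- X[, , trials, drop = FALSE]
  cfg <- attr(forecaster, "config")
  S <- if (is.null(tags_in))
    array(0, c(cfg$tag_dim, dim(X)[2], dim(X)[3]))
  else tags_in[, , trials, drop = FALSE]
  n <- dim(X)[3]; Zd <- cfg$latent; Tb <- dim(X)[2]
  opt <- adam_init(forecaster)
  loss_log <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "fc_epoch", ep), sample(n))
    tot <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1, n)]
      eps <- with_seed(derive_seed(seed, "fc_eps", ep, b0),
                       array(rnorm(length(bi) * Zd * Tb),
                             c(length(bi), Zd, Tb)))
      fw <- srnn_forward(forecaster, X[, , bi, drop = FALSE],
                         S[, , bi, drop = FALSE], eps)
      gr <- srnn_backward(forecaster, fw)
      up <- adam_step(forecaster, gr, opt, lr = lr)
      atts <- attributes(forecaster)
      forecaster <- up$params
      attributes(forecaster) <- atts
      opt <- up$state
      tot <- tot + fw$loss * length(bi)
    }
    loss_log[ep] <- tot / n
  }
  list(forecaster = forecaster, log = loss_log)
}

## ---- sequence-task (dual component) training ------------------------------

#' Create the dual-component sequence-task agent
#'
#' A state-representation component (transformer encoder + linear
#' choice-classification head, trained with cross-entropy on the monkey's
#' choice) and a Q component (2-layer ReLU head on the representation
#' concatenated with the last-action one-hot), trained with the RL loss
#' against a softly-updated target network.
#'
#' @inheritParams core_agent
#' @param head_hidden hidden width of the Q head.
#' @export
sequence_agent <- function(n_cells, n_bins = 12, d_model = 100,
                           n_heads = 4, d_ff = 200, n_layers = 2,
                           head_hidden = 64, seed = 1) {
  enc <- core_agent(n_cells, n_bins, n_actions = 2, d_model = d_model,
                    n_heads = n_heads, d_ff = d_ff, n_layers = n_layers,
                    seed = derive_seed(seed, "enc"))
  qnet <- mlp_init(c(d_model + 4, head_hidden, 4),
                   seed = derive_seed(seed, "qnet"), zero_last = TRUE)
  structure(list(encoder = enc, qnet = qnet, qnet_target = qnet,
                 config = list(n_cells = n_cells, n_bins = n_bins)),
            class = "sequence_agent")
}

#' Train the sequence-task agent (dual optimizers)
#'
#' @param env a [env_sequence()].
#' @param agent a [sequence_agent()].
#' @param config a [train_config()]; the sequence task uses
#'   `discount = 0.99` and, in value-mapped mode, a conservative
#'   regularizer `cql_weight * (logsumexp(Q) - Q(s, a))`.
#' @return list: `agent`, `log`.
#' @export
train_env2_agent <- function(env, agent, config = train_config(
                               n_iterations = 170, discount = 0.99)) {
  feats <- env$features
  g <- config$discount
  opt_enc <- list(tf = adam_init(agent$encoder$tf),
                  head = adam_init(agent$encoder$head))
  opt_q <- adam_init(agent$qnet)
  # buffer rows: trial, step, last_action, action, reward, terminal
  buf <- replay_buffer(config$buffer_capacity, n_cols = 6)
  log <- data.frame(iteration = integer(), q_loss = numeric(),
                    ce_loss = numeric(), reward_rate = numeric(),
                    buffer_size = integer())
  for (it in seq_len(config$n_iterations)) {
    rew_tot <- 0; rew_max <- 0
    ep_trials <- integer(0)
    for (ep in seq_len(config$n_episodes)) {
      env$reset()
      idx <- env$order
      ep_trials <- c(ep_trials, idx)
      chi <- core_forward(agent$encoder, feats[, , idx, drop = FALSE])$chi
      rng_seed <- derive_seed(config$seed, "act", it, ep)
      with_seed(rng_seed, {
        active <- seq_along(idx)
        last_a <- rep(0L, length(idx))
        for (stp in 0:3) {
          if (!length(active)) break
          sa <- cbind(chi[active, , drop = FALSE], onehot(last_a[active], 4))
          q <- mlp_forward(agent$qnet, sa)$out
          a <- sample_actions(boltzmann_policy(q, config$tau))
          tgt <- vapply(idx[active], function(i) env$map[env$key[i], stp + 1],
                        0L)
          r <- as.numeric(a == tgt)
          term <- (r == 0) | (stp == 3)
          buf$add(cbind(idx[active], stp, last_a[active], a, r,
                        as.numeric(term)))
          rew_tot <- rew_tot + sum(r)
          keep <- !term
          last_a[active[keep]] <- a[keep]
          active <- active[keep]
        }
      })
      rew_max <- rew_max + 4 * length(idx)
    }
    # --- encoder update: supervised cross-entropy on the monkey's choice
    enc_idx <- with_seed(derive_seed(config$seed, "enc", it),
                         sample(ep_trials, min(config$batch_size,
                                               length(ep_trials))))
    fw <- core_forward(agent$encoder, feats[, , enc_idx, drop = FALSE])
    y <- onehot(env$choice[enc_idx], 2)
    pr <- softmax_rows(fw$q)
    ce <- -mean(log(pr[y == 1] + 1e-12))
    dq <- (pr - y) / length(enc_idx)
    gb <- core_backward(agent$encoder, feats[, , enc_idx, drop = FALSE], dq,
                        fw = fw)
    for (nm in c("tf", "head")) {
      up <- adam_step(agent$encoder[[nm]], gb[[nm]], opt_enc[[nm]],
                      lr = config$lr)
      atts <- attributes(agent$encoder[[nm]])
      agent$encoder[[nm]] <- up$params
      attributes(agent$encoder[[nm]]) <- atts
      opt_enc[[nm]] <- up$state
    }
    # --- Q update from replay
    batch <- with_seed(derive_seed(config$seed, "sample", it),
                       buf$sample(config$batch_size))
    q_loss <- NA_real_
    if (!is.null(batch)) {
      K <- nrow(batch)
      bt <- batch[, 1]; bstep <- batch[, 2]; blast <- batch[, 3]
      ba <- batch[, 4]; br <- batch[, 5]; bterm <- batch[, 6] > 0
      chi_b <- core_forward(agent$encoder, feats[, , bt, drop = FALSE])$chi
      s <- cbind(chi_b, onehot(as.integer(blast), 4))
      fwq <- mlp_forward(agent$qnet, s)
      sel <- cbind(seq_len(K), as.integer(ba))
      tgt <- br
      if (any(!bterm) && g > 0) {
        sn <- cbind(chi_b[!bterm, , drop = FALSE],
                    onehot(as.integer(ba[!bterm]), 4))
        qn <- mlp_forward(agent$qnet_target, sn)$out
        tgt[!bterm] <- br[!bterm] + g * apply(qn, 1, max)
      }
      err <- fwq$out[sel] - tgt
      q_loss <- mean(err^2)
      dq <- matrix(0, K, 4)
      dq[sel] <- 2 * err / K
      if (config$cql_weight > 0) {
        pq <- softmax_rows(fwq$out)
        dq <- dq + config$cql_weight * (pq - onehot(as.integer(ba), 4)) / K
        q_loss <- q_loss + config$cql_weight *
          mean(log(rowSums(exp(fwq$out))) - fwq$out[sel])
      }
      qb <- mlp_backward(agent$qnet, fwq$cache, dq)
      up <- adam_step(agent$qnet, qb$grads, opt_q, lr = config$lr)
      atts <- attributes(agent$qnet)
      agent$qnet <- up$params
      attributes(agent$qnet) <- atts
      opt_q <- up$state
      agent$qnet_target <- soft_update(agent$qnet_target, agent$qnet,
                                       config$rho)
      attr(agent$qnet_target, "n_layers") <- 2L
    }
    log <- rbind(log, data.frame(iteration = it, q_loss = q_loss,
                                 ce_loss = ce,
                                 reward_rate = rew_tot / rew_max,
                                 buffer_size = buf$size()))
  }
  list(agent = agent, log = log)
}

#' Greedy evaluation of a sequence agent
#'
#' Runs the trained agent greedily through an [env_sequence()] for
#' `n_episodes` episodes and reports mean normalized reward, plus the
#' choice-decoding accuracy of the state-representation component.
#'
#' @param agent trained [sequence_agent()].
#' @param env evaluation environment.
#' @param n_episodes episodes to average.
#' @export
evaluate_env2_agent <- function(agent, env, n_episodes = 5) {
  rew <- numeric(n_episodes)
  correct <- total <- 0
  for (ep in seq_len(n_episodes)) {
    env$reset()
    idx <- env$order
    fw <- core_forward(agent$encoder, env$features[, , idx, drop = FALSE])
    pred <- max.col(fw$q, ties.method = "first")
    correct <- correct + sum(pred == env$choice[idx]); total <- total + length(idx)
    rtot <- 0
    for (j in seq_along(idx)) {
      last_a <- 0L
      for (stp in 0:3) {
        sa <- cbind(fw$chi[j, , drop = FALSE], onehot(last_a, 4))
        a <- which.max(mlp_forward(agent$qnet, sa)$out)
        tgt <- env$map[env$key[idx[j]], stp + 1]
        if (a != tgt) break
        rtot <- rtot + 1
        last_a <- as.integer(a)
      }
    }
    rew[ep] <- rtot / (4 * length(idx))
  }
  list(normalized_reward = mean(rew), choice_accuracy = correct / total)
}
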