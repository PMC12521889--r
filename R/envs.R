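# The three hypothetical decision environments, as step-based interfaces
# over a preprocessed session.  States expose scaled spike tensors (plus,
# for the sequence environment, the last executed action as a one-hot, and
# for the masked environment, stimulus labels and a prefix cutoff).
#
# Environments are R environments (mutable closures).  An episode is one
# pass over a without-replacement sample of `episode_length` trials from
# the trial pool, shuffled per episode; episode draws are reproducible
# from the environment seed.

new_env_base <- function(kind, features, choice, episode_length, seed) {
  e <- new.env(parent = emptyenv())
  e$kind <- kind
  e$features <- features          # cells x bins x pool
  e$choice <- choice              # 1 = first-viewed, 2 = second-viewed
  e$n_pool <- dim(features)[3]
  e$n_bins <- dim(features)[2]
  e$episode_length <- min(episode_length, e$n_pool)
  e$seed <- seed
  e$episode_count <- 0L
  e$order <- integer(0)
  e$ptr <- 0L
  e
}

episode_reset <- function(e) {
  e$episode_count <- e$episode_count + 1L
  e$order <- with_seed(derive_seed(e$seed, "episode", e$episode_count),
                       sample(e$n_pool, e$episode_length))
  if (!is.null(e$aug))
    e$features[, , e$aug$cols] <- with_seed(
      derive_seed(e$seed, "aug", e$episode_count),
      pmin(pmax(e$aug$base + array(runif(length(e$aug$base),
                                         -e$aug$noise_bound,
                                         e$aug$noise_bound),
                                   dim(e$aug$base)), -1), 1))
  e$ptr <- 1L
  invisible(e)
}

#' Redraw augmentation noise every episode
#'
#' By default synthetic training trials are generated once (`fixed`
#' mode).  This switches an environment to `per_episode` mode: the noise
#' of the designated pool entries is redrawn from
#' `Uniform(-noise_bound, noise_bound)` (and clipped) at every episode
#' reset, reproducibly from the environment seed.
#'
#' @param env a valdec environment.
#' @param cols indices (into the trial pool) of the synthetic copies.
#' @param base the noise-free scaled features of those entries,
#'   `[cells x bins x length(cols)]`.
#' @param noise_bound uniform half-width.
#' @return the environment, invisibly.
#' @export
set_per_episode_augmentation <- function(env, cols, base,
                                         noise_bound = 0.1) {
  stopifnot(length(cols) == dim(base)[3])
  env$aug <- list(cols = cols, base = base, noise_bound = noise_bound)
  invisible(env)
}

#' Choice-prediction environment (single-step trials)
#'
#' The agent observes one trial's scaled spike tensor and predicts which
#' option the monkey chose; reward is +1 for a correct prediction, 0
#' otherwise, and the next trial is presented.
#'
#' @param features `cells x bins x trials` scaled pool (training or test).
#' @param choice per-trial recorded choice (1 = first-viewed, 2 = second).
#' @param episode_length trials per episode (shuffled, without replacement).
#' @param seed environment seed; episode draws derive from it.
#' @return an environment with `$reset()`, `$observe()`, `$step(action)`.
#' @export
env_choice <- function(features, choice, episode_length = 128, seed = 1) {
  e <- new_env_base("env1", features, choice, episode_length, seed)
  e$n_actions <- 2L
  e$reset <- function() { episode_reset(e); invisible(NULL) }
  e$observe <- function() {
    if (e$ptr > e$episode_length) return(NULL)
    list(x = e$features[, , e$order[e$ptr]], trial = e$order[e$ptr])
  }
  e$step <- function(action) {
    if (!action %in% 1:2) stop("action must be 1 or 2")
    i <- e$order[e$ptr]
    r <- as.numeric(action == e$choice[i])
    e$ptr <- e$ptr + 1L
    done <- e$ptr > e$episode_length
    s_next <- if (done) NULL else e$features[, , e$order[e$ptr]]
    list(s = e$features[, , i], s_next = s_next, r = r, a = action,
         done = done)
  }
  e$max_reward_per_episode <- function() e$episode_length
  class(e) <- c("valdec_env", "environment")
  e
}

#' Build the key -> action-sequence map for the sequence environment
#'
#' Keys are either the five value levels (`mode = "value"`) or the two
#' viewing orders (`mode = "order"`); each key gets a distinct random
#' sequence of 4 actions from a 4-action alphabet, fixed by seed.
#'
#' @param mode `"order"` or `"value"`.
#' @param seq_len sequence length (4).
#' @param n_actions alphabet size (4).
#' @param seed RNG seed.
#' @return matrix `n_keys x seq_len` of actions in `1..n_actions`.
#' @export
sequence_map <- function(mode = c("order", "value"), seq_len = 4,
                         n_actions = 4, seed = 1) {
  mode <- match.arg(mode)
  n_keys <- if (mode == "order") 2L else 5L
  with_seed(derive_seed(seed, "seqmap"), {
    seqs <- matrix(0L, 0, seq_len)
    while (nrow(seqs) < n_keys) {
      cand <- sample(n_actions, seq_len, replace = TRUE)
      if (!any(apply(seqs, 1, identical, y = cand))) seqs <- rbind(seqs, cand)
    }
    rownames(seqs) <- NULL
    seqs
  })
}

#' Sequence-execution environment (multi-step trials)
#'
#' On each trial the agent must emit the 4-action sequence mapped to the
#' chosen target's key (its value level, or its viewing order).  Each
#' correct action earns +1; a mistake ends the trial with no further
#' reward, so per-trial reward lies in 0..4.  The state is the trial's
#' spike tensor plus the last executed action as a 4-dim one-hot (zero
#' vector at trial start).
#'
#' @inheritParams env_choice
#' @param values per-trial value level of the *chosen* target (for
#'   `mode = "value"`).
#' @param mode key type: `"order"` (2 sequences) or `"value"` (5).
#' @param seq_map optional precomputed [sequence_map()].
#' @export
env_sequence <- function(features, choice, values = NULL,
                         mode = c("order", "value"),
                         episode_length = 128, seed = 1, seq_map = NULL) {
  mode <- match.arg(mode)
  if (mode == "value" && is.null(values))
    stop("configuration error: value-mapped mode needs chosen-target values")
  e <- new_env_base("env2", features, choice, episode_length, seed)
  e$n_actions <- 4L
  e$seq_len <- 4L
  e$mode <- mode
  e$map <- seq_map %||% sequence_map(mode, seed = seed)
  e$key <- if (mode == "order") choice else values
  e$step_in_trial <- 0L
  e$last_action <- 0L
  e$reset <- function() {
    episode_reset(e); e$step_in_trial <- 0L; e$last_action <- 0L
    invisible(NULL)
  }
  e$observe <- function() {
    if (e$ptr > e$episode_length) return(NULL)
    i <- e$order[e$ptr]
    list(x = e$features[, , i], trial = i,
         last_action = as.vector(onehot(e$last_action, 4L)),
         step = e$step_in_trial)
  }
  e$target_sequence <- function(trial) e$map[e$key[trial], ]
  e$step <- function(action) {
    if (!action %in% seq_len(e$n_actions)) stop("action out of range")
    i <- e$order[e$ptr]
    tgt <- e$map[e$key[i], e$step_in_trial + 1L]
    correct <- action == tgt
    r <- as.numeric(correct)
    s <- list(trial = i, last_action = e$last_action, step = e$step_in_trial)
    if (correct && e$step_in_trial + 1L < e$seq_len) {
      e$step_in_trial <- e$step_in_trial + 1L
      e$last_action <- as.integer(action)
      trial_done <- FALSE
    } else {
      trial_done <- TRUE                       # mistake, or full sequence
      e$step_in_trial <- 0L
      e$last_action <- 0L
      e$ptr <- e$ptr + 1L
    }
    done <- e$ptr > e$episode_length
    list(s = s, r = r, a = action, trial_done = trial_done, done = done)
  }
  e$max_reward_per_episode <- function() e$seq_len * e$episode_length
  class(e) <- c("valdec_env", "environment")
  e
}

#' Masked (early-prediction) choice environment
#'
#' As [env_choice()], but each trial exposes only a contiguous prefix of
#' time bins, with the cutoff sampled per trial.  States also carry the
#' first/second stimulus labels so that stimulus-conditioned forecasting
#' agents can be trained.  Non-contiguous masks are disallowed.
#'
#' @inheritParams env_choice
#' @param stim_first,stim_second per-trial stimulus ids.
#' @param cutoff `"uniform"` (sampled over 1..n_bins per trial) or
#'   `"fixed:k"` / an integer for a constant cutoff.
#' @export
env_masked <- function(features, choice, stim_first, stim_second,
                       episode_length = 128, cutoff = "uniform", seed = 1) {
  e <- new_env_base("env3", features, choice, episode_length, seed)
  e$n_actions <- 2L
  e$stim_first <- stim_first
  e$stim_second <- stim_second
  if (is.character(cutoff) && grepl("^fixed:", cutoff))
    cutoff <- as.integer(sub("fixed:", "", cutoff))
  if (!identical(cutoff, "uniform") &&
      (!is.numeric(cutoff) || is.na(cutoff) || cutoff < 1 ||
         cutoff > e$n_bins))
    stop("configuration error: cutoff must be 'uniform' or 'fixed:k' ",
         "with 1 <= k <= n_bins (masks are always contiguous prefixes; ",
         "non-contiguous masks are disallowed)")
  e$cutoff_mode <- cutoff
  e$cutoffs <- integer(0)
  e$sample_cutoffs <- function(k) {
    if (identical(e$cutoff_mode, "uniform"))
      sample(e$n_bins, k, replace = TRUE)
    else rep(as.integer(e$cutoff_mode), k)
  }
  e$reset <- function() {
    episode_reset(e)
    e$cutoffs <- with_seed(derive_seed(e$seed, "cutoff", e$episode_count),
                           e$sample_cutoffs(e$episode_length))
    invisible(NULL)
  }
  e$observe <- function() {
    if (e$ptr > e$episode_length) return(NULL)
    i <- e$order[e$ptr]
    ct <- e$cutoffs[e$ptr]
    list(x = e$features[, , i], trial = i, cutoff = ct,
         mask = as.integer(seq_len(e$n_bins) <= ct),
         stim_first = e$stim_first[i], stim_second = e$stim_second[i])
  }
  e$step <- function(action) {
    if (!action %in% 1:2) stop("action must be 1 or 2")
    i <- e$order[e$ptr]
    r <- as.numeric(action == e$choice[i])
    e$ptr <- e$ptr + 1L
    done <- e$ptr > e$episode_length
    list(s = i, r = r, a = action, done = done)
  }
  e$max_reward_per_episode <- function() e$episode_length
  class(e) <- c("valdec_env", "environment")
  e
}

#' Monte-Carlo chance level of a uniform-random agent
#'
#' Runs a uniform-random policy for `n_episodes` episodes and reports the
#' mean reward normalized by the environment's maximum per-episode reward
#' (sequence length x number of trials for the sequence environment).
#'
#' @param env a valdec environment.
#' @param n_episodes number of episodes (default 100).
#' @param seed RNG seed for the random policy.
#' @return mean normalized reward.
#' @export
random_agent_baseline <- function(env, n_episodes = 100, seed = 1) {
  tot <- numeric(n_episodes)
  with_seed(derive_seed(seed, "random_agent"), {
    for (ep in seq_len(n_episodes)) {
      env$reset()
      done <- FALSE; rew <- 0
      while (!done) {
        st <- env$step(sample(env$n_actions, 1))
        rew <- rew + st$r
        done <- st$done
      }
      tot[ep] <- rew / env$max_reward_per_episode()
    }
  })
  mean(tot)
}
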