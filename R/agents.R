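# Q-decoding agents.
#
# The core agent reads a trial's scaled spike tensor through the
# transformer encoder, extracts the class-token representation chi_1, and
# maps it with a linear head to one Q value per action.  The combined
# (forecasting) agent runs two encoders -- one over the real prefix of
# bins, one over forecasted bins -- concatenates the two class tokens and
# maps them with a linear fusion head; either path can be ablated by
# zeroing its representation.

#' Create a core transformer Q-decoder
#'
#' @param n_cells,n_bins input dimensions.
#' @param n_actions size of the action set (2 for choice prediction).
#' @param d_model,n_heads,d_ff,n_layers encoder hyper-parameters.
#' @param head `"linear"` (default) or `"mlp"` (2-layer ReLU head, used by
#'   the sequence-task agent variant).
#' @param head_hidden hidden width of the mlp head.
#' @param seed initialization seed.
#' @return object of class `core_agent`.
#' @export
core_agent <- function(n_cells, n_bins = 12, n_actions = 2,
                       d_model = 100, n_heads = 4, d_ff = 200, n_layers = 2,
                       head = c("linear", "mlp"), head_hidden = 64,
                       seed = 1) {
  head <- match.arg(head)
  tf <- tf_init(n_cells, d_model, n_heads, d_ff, n_layers,
                seed = derive_seed(seed, "tf"))
  hd <- if (head == "linear")
    mlp_init(c(d_model, n_actions), seed = derive_seed(seed, "head"),
             zero_last = TRUE)
  else
    mlp_init(c(d_model, head_hidden, n_actions),
             seed = derive_seed(seed, "head"), zero_last = TRUE)
  structure(list(tf = tf, head = hd,
                 config = list(n_cells = n_cells, n_bins = n_bins,
                               n_actions = n_actions, d_model = d_model,
                               head = head)),
            class = "core_agent")
}

#' Core agent forward pass: Q values from one or more trials
#'
#' @param agent a `core_agent`.
#' @param X `[cells x bins]` or `[cells x bins x trials]` scaled input.
#' @param mask optional `[trials x bins]` (or vector) 0/1 visibility mask;
#'   Q values are exactly invariant to the content of masked-out bins.
#' @param return_attn also return attention tensors.
#' @return list: `q` (`trials x n_actions`), `chi` (`trials x d_model`
#'   class-token representation), optionally `attn`.
#' @export
core_forward <- function(agent, X, mask = NULL, return_attn = FALSE,
                         keep_state = FALSE) {
  fw <- tf_forward(agent$tf, X, mask, return_attn, want_state = keep_state)
  hd <- mlp_forward(agent$head, fw$chi)
  out <- list(q = hd$out, chi = fw$chi, head_cache = hd$cache,
              state = fw$state)
  if (return_attn) out$attn <- fw$attn
  out
}

# backward: dq (trials x n_actions) -> grads for tf + head (+ input grads).
# reuses fw$state when the forward pass kept it.
core_backward <- function(agent, X, dq, mask = NULL, fw = NULL,
                          want_dx = FALSE) {
  if (is.null(fw)) fw <- core_forward(agent, X, mask)
  hb <- mlp_backward(agent$head, fw$head_cache, dq)
  tb <- if (!is.null(fw$state))
    tf_backward_state(agent$tf, fw$state, hb$dX)
  else tf_backward(agent$tf, X, hb$dX, mask)
  list(tf = tb$grads, head = hb$grads, dX = if (want_dx) tb$dX)
}

#' Boltzmann (softmax) exploration policy
#'
#' `p(a | s) = exp(Q(s, a) / tau) / sum_a' exp(Q(s, a') / tau)`.
#'
#' @param q numeric vector of Q values, or a `trials x actions` matrix.
#' @param tau temperature (> 0), default 1.
#' @return action probabilities with the same shape as `q` rows.
#' @export
boltzmann_policy <- function(q, tau = 1) {
  if (tau <= 0) stop("tau must be > 0")
  vec <- is.null(dim(q))
  p <- softmax_rows(if (vec) matrix(q, 1) else q / tau)
  if (vec) p <- drop(softmax_rows(matrix(q / tau, 1)))
  p
}

# sample one action per row of a probability matrix (uses the caller's RNG)
sample_actions <- function(p) {
  u <- runif(nrow(p))
  cum <- t(apply(p, 1, cumsum))
  pmin(rowSums(cum < u) + 1L, ncol(p))
}

## ---- combined (forecasting) agent -----------------------------------------

#' Create a combined agent: core path + forecasting path
#'
#' @inheritParams core_agent
#' @param forecaster a trained (frozen) forecaster from [srnn_init()] /
#'   [train_forecaster()].
#' @param tags a `stimulus_tags` table ([stimulus_tags()]); `NULL` for a
#'   NOSTIM agent (zero tags).
#' @return object of class `combined_agent`; the forecaster inside is
#'   never updated by agent training.
#' @export
combined_agent <- function(n_cells, n_bins, forecaster, tags = NULL,
                           n_actions = 2, d_model = 100, n_heads = 4,
                           d_ff = 200, n_layers = 2, seed = 1) {
  tf_core <- tf_init(n_cells, d_model, n_heads, d_ff, n_layers,
                     seed = derive_seed(seed, "core"))
  tf_fore <- tf_init(n_cells, d_model, n_heads, d_ff, n_layers,
                     seed = derive_seed(seed, "fore"))
  fusion <- mlp_init(c(2 * d_model, n_actions),
                     seed = derive_seed(seed, "fusion"), zero_last = TRUE)
  structure(list(tf_core = tf_core, tf_fore = tf_fore, fusion = fusion,
                 forecaster = forecaster, tags = tags,
                 config = list(n_cells = n_cells, n_bins = n_bins,
                               n_actions = n_actions, d_model = d_model,
                               stim = !is.null(tags))),
            class = "combined_agent")
}

#' Combined agent forward pass under dual attention masking
#'
#' The core path attends only to real bins `1..cutoff`; the forecasting
#' path attends only to forecasted bins `cutoff+1..n_bins`.  The two class
#' tokens are concatenated and mapped by a linear fusion head.
#'
#' @param agent a `combined_agent`.
#' @param X real scaled input `[cells x bins x trials]`.
#' @param cutoffs integer vector (or scalar) of per-trial cutoffs.
#' @param forecasts forecasted tensor `[cells x bins x trials]` (bins
#'   `<= cutoff` may hold anything; they are masked out).  Usually comes
#'   from [forecast_fill()].
#' @param ablation one of `"none"`, `"no_core"`, `"no_forecast"`
#'   (`"no_stimvec"` is applied upstream by forecasting with zero tags).
#' @return list with `q`, `chi_core`, `chi_fore` and caches.
#' @export
combined_forward <- function(agent, X, cutoffs, forecasts,
                             ablation = c("none", "no_core", "no_forecast"),
                             keep_state = FALSE) {
  ablation <- match.arg(ablation)
  X <- as_trial_array(X); forecasts <- as_trial_array(forecasts)
  B <- dim(X)[3]; Tb <- dim(X)[2]
  cutoffs <- rep_len(cutoffs, B)
  core_mask <- t(vapply(cutoffs, function(ct) as.integer(seq_len(Tb) <= ct),
                        integer(Tb)))
  fore_mask <- 1L - core_mask
  # at full cutoff the forecasting path has nothing to attend to except the
  # class token; its mask is all-zero there, which is well-defined
  fc <- tf_forward(agent$tf_core, X, core_mask, want_state = keep_state)
  ff <- tf_forward(agent$tf_fore, forecasts, fore_mask,
                   want_state = keep_state)
  chi_core <- fc$chi; chi_fore <- ff$chi
  if (ablation == "no_core") chi_core <- chi_core * 0
  if (ablation == "no_forecast") chi_fore <- chi_fore * 0
  hd <- mlp_forward(agent$fusion, cbind(chi_core, chi_fore))
  list(q = hd$out, chi_core = chi_core, chi_fore = chi_fore,
       head_cache = hd$cache, core_mask = core_mask, fore_mask = fore_mask,
       ablation = ablation, state_core = fc$state, state_fore = ff$state)
}

combined_backward <- function(agent, X, forecasts, fw, dq) {
  D <- agent$config$d_model
  hb <- mlp_backward(agent$fusion, fw$head_cache, dq)
  dchi_core <- hb$dX[, seq_len(D), drop = FALSE]
  dchi_fore <- hb$dX[, D + seq_len(D), drop = FALSE]
  if (fw$ablation == "no_core") dchi_core <- dchi_core * 0
  if (fw$ablation == "no_forecast") dchi_fore <- dchi_fore * 0
  gc_ <- if (!is.null(fw$state_core))
    tf_backward_state(agent$tf_core, fw$state_core, dchi_core)
  else tf_backward(agent$tf_core, as_trial_array(X), dchi_core, fw$core_mask)
  gf_ <- if (!is.null(fw$state_fore))
    tf_backward_state(agent$tf_fore, fw$state_fore, dchi_fore)
  else tf_backward(agent$tf_fore, as_trial_array(forecasts), dchi_fore,
                   fw$fore_mask)
  list(tf_core = gc_$grads, tf_fore = gf_$grads, fusion = hb$grads)
}

# deterministic checksum over a parameter list (freezing contract tests)
params_checksum <- function(p) {
  sum(vapply(p, function(x) sum(as.numeric(x) * seq_along(x)), 0))
}
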