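# Native neural-network primitives: transformer encoder wrappers around the
# compiled kernel, dense layers, a plain recurrent layer, and Adam.
# Gradients are exact and finite-difference-checked in the test suite.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize transformer-encoder parameters
#'
#' Builds the parameter set of the encoder used by the Q-decoder: a linear
#' embedding of the per-bin population vector, a learned class token, and
#' `n_layers` post-LN encoder layers (multi-head attention + ReLU MLP).
#'
#' @param n_cells cells per trial (embedding input dimension).
#' @param d_model token dimension (default 100).
#' @param n_heads attention heads (default 4).
#' @param d_ff feed-forward width (default 200).
#' @param n_layers encoder layers (default 2).
#' @param seed RNG seed for the initialization draw.
#' @return named list of parameter arrays consumed by the compiled kernel.
#' @export
tf_init <- function(n_cells, d_model = 100, n_heads = 4, d_ff = 200,
                    n_layers = 2, seed = 1) {
  with_seed(seed, {
    p <- list(
      W_e = glorot(n_cells, d_model),
      b_e = numeric(d_model),
      cls = rnorm(d_model) * 0.02
    )
    for (l in seq_len(n_layers)) {
      nm <- function(s) paste0("l", l, "_", s)
      p[[nm("Wq")]] <- glorot(d_model, d_model); p[[nm("bq")]] <- numeric(d_model)
      p[[nm("Wk")]] <- glorot(d_model, d_model); p[[nm("bk")]] <- numeric(d_model)
      p[[nm("Wv")]] <- glorot(d_model, d_model); p[[nm("bv")]] <- numeric(d_model)
      p[[nm("Wo")]] <- glorot(d_model, d_model); p[[nm("bo")]] <- numeric(d_model)
      p[[nm("W1")]] <- glorot(d_model, d_ff);    p[[nm("c1")]] <- numeric(d_ff)
      p[[nm("W2")]] <- glorot(d_ff, d_model);    p[[nm("c2")]] <- numeric(d_model)
      p[[nm("ln1_g")]] <- rep(1, d_model); p[[nm("ln1_b")]] <- numeric(d_model)
      p[[nm("ln2_g")]] <- rep(1, d_model); p[[nm("ln2_b")]] <- numeric(d_model)
    }
    attr(p, "config") <- list(n_cells = n_cells, d_model = d_model,
                              n_heads = n_heads, d_ff = d_ff,
                              n_layers = n_layers)
    p
  })
}

# mask: NULL (all bins visible) or logical/0-1 matrix [trials x bins]
tf_mask <- function(mask, n_bins, n_trials) {
  if (is.null(mask)) return(matrix(1L, n_bins, n_trials))
  if (is.null(dim(mask))) mask <- matrix(mask, nrow = 1)
  stopifnot(ncol(mask) == n_bins)
  storage.mode(mask) <- "integer"
  t(mask)
}

#' Transformer encoder forward pass
#'
#' @param params from [tf_init()].
#' @param X spike features, `[cells x bins]` or `[cells x bins x trials]`,
#'   expected in `[-1, 1]`.
#' @param mask optional `[trials x bins]` 0/1 matrix of attendable bins
#'   (1 = visible).  The class token is always visible; predictions are
#'   exactly invariant to the content of masked bins.
#' @param return_attn also return per-layer attention tensors.
#' @param want_state keep the kernel's forward state so a following
#'   [tf_backward_state()] can skip the forward recomputation.
#' @return list with `chi` (`trials x d_model` class-token representations)
#'   and optionally `attn` / `state`.
#' @export
tf_forward <- function(params, X, mask = NULL, return_attn = FALSE,
                       want_state = FALSE) {
  cfg <- attr(params, "config")
  X <- as_trial_array(X)
  stopifnot(dim(X)[1] == cfg$n_cells)
  m <- tf_mask(mask, dim(X)[2], dim(X)[3])
  out <- tf_kernel(params, X, m, cfg$n_heads, cfg$n_layers,
                   NULL, return_attn, want_state)
  res <- list(chi = t(out$chi))
  if (return_attn) res$attn <- out$attn
  if (want_state) res$state <- out$state
  res
}

#' Backward pass from a cached forward state
#' @param params the parameter list used in the forward pass.
#' @param state the `state` handle from `tf_forward(want_state = TRUE)`.
#' @param dchi gradient w.r.t. `chi`, `trials x d_model`.
#' @return as [tf_backward()].
#' @export
tf_backward_state <- function(params, state, dchi) {
  out <- tf_kernel_grad(state, t(dchi))
  list(grads = out$grads[names(params)], dX = out$dX)
}

#' Transformer encoder backward pass
#'
#' @param dchi gradient of the loss w.r.t. `chi`, `trials x d_model`.
#' @inheritParams tf_forward
#' @return list with `grads` (named like `params`) and `dX`
#'   (`cells x bins x trials` input gradient, used for attribution).
#' @export
tf_backward <- function(params, X, dchi, mask = NULL) {
  cfg <- attr(params, "config")
  X <- as_trial_array(X)
  m <- tf_mask(mask, dim(X)[2], dim(X)[3])
  out <- tf_kernel(params, X, m, cfg$n_heads, cfg$n_layers,
                   t(dchi), FALSE)
  g <- out$grads
  # kernel returns biases as plain vectors; ensure shapes match params
  list(grads = g[names(params)], dX = out$dX)
}

## ---- dense (MLP) stack ----------------------------------------------------

# sizes: c(n_in, h1, ..., n_out); hidden activations ReLU, linear output
mlp_init <- function(sizes, seed = 1, zero_last = FALSE) {
  with_seed(seed, {
    L <- length(sizes) - 1
    p <- list()
    for (l in seq_len(L)) {
      W <- glorot(sizes[l], sizes[l + 1])
      if (zero_last && l == L) W[] <- 0
      p[[paste0("W", l)]] <- W
      p[[paste0("b", l)]] <- numeric(sizes[l + 1])
    }
    attr(p, "n_layers") <- L
    p
  })
}

mlp_forward <- function(p, X) {
  L <- attr(p, "n_layers")
  cache <- list(X)
  H <- X
  for (l in seq_len(L)) {
    H <- H %*% p[[paste0("W", l)]] +
      matrix(p[[paste0("b", l)]], nrow(H), length(p[[paste0("b", l)]]), byrow = TRUE)
    if (l < L) H <- pmax(H, 0)
    cache[[l + 1]] <- H
  }
  list(out = H, cache = cache)
}

mlp_backward <- function(p, cache, dout) {
  L <- attr(p, "n_layers")
  g <- list()
  dH <- dout
  for (l in rev(seq_len(L))) {
    if (l < L) dH <- dH * (cache[[l + 1]] > 0)
    g[[paste0("W", l)]] <- t(cache[[l]]) %*% dH
    g[[paste0("b", l)]] <- colSums(dH)
    dH <- dH %*% t(p[[paste0("W", l)]])
  }
  list(grads = g[names(p)], dX = dH)
}

## ---- plain tanh recurrent layer -------------------------------------------

rnn_init <- function(n_in, n_hidden, n_out, seed = 1) {
  with_seed(seed, list(
    W_ih = glorot(n_in, n_hidden),
    W_hh = glorot(n_hidden, n_hidden),
    b_h  = numeric(n_hidden),
    W_out = matrix(0, n_hidden, n_out),
    b_out = numeric(n_out)
  ))
}

# X: [cells x bins x trials]; returns logits from the last hidden state
rnn_forward <- function(p, X) {
  X <- as_trial_array(X)
  B <- dim(X)[3]; Tb <- dim(X)[2]
  H <- matrix(0, B, ncol(p$W_ih))
  hs <- vector("list", Tb); xs <- vector("list", Tb)
  for (t in seq_len(Tb)) {
    xt <- t(X[, t, , drop = TRUE])
    if (B == 1) xt <- matrix(X[, t, 1], 1)
    H <- tanh(xt %*% p$W_ih + H %*% p$W_hh +
                matrix(p$b_h, B, length(p$b_h), byrow = TRUE))
    hs[[t]] <- H; xs[[t]] <- xt
  }
  out <- H %*% p$W_out + matrix(p$b_out, B, length(p$b_out), byrow = TRUE)
  list(out = out, hs = hs, xs = xs)
}

rnn_backward <- function(p, fwd, dout) {
  Tb <- length(fwd$hs)
  g <- lapply(p, function(x) x * 0)
  Hlast <- fwd$hs[[Tb]]
  g$W_out <- t(Hlast) %*% dout
  g$b_out <- colSums(dout)
  dH <- dout %*% t(p$W_out)
  for (t in rev(seq_len(Tb))) {
    da <- dH * (1 - fwd$hs[[t]]^2)
    g$W_ih <- g$W_ih + t(fwd$xs[[t]]) %*% da
    hprev <- if (t > 1) fwd$hs[[t - 1]] else 0 * fwd$hs[[t]]
    g$W_hh <- g$W_hh + t(hprev) %*% da
    g$b_h <- g$b_h + colSums(da)
    dH <- da %*% t(p$W_hh)
  }
  g
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

#' One Adam update
#'
#' @param params,grads named lists of conformable arrays.
#' @param state from [adam_init()].
#' @param lr learning rate.
#' @param beta1,beta2,eps usual Adam constants.
#' @param clip optional global-norm gradient clip.
#' @return list(params, state).
#' @keywords internal
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8, clip = 5) {
  if (!is.null(clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
    if (is.finite(gn) && gn > clip)
      grads <- lapply(grads, function(g) g * (clip / gn))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
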