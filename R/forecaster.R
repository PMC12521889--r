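# Stochastic recurrent forecaster of scaled neural activity.
#
# A variational recurrent model: a tanh recurrence d_h over the previous
# activity x_{t-1} concatenated with a stimulus tag s_{t-1}; a conditional
# *prior* d_z mapping (z_{t-1}, h_t) to the mean/sd of a diagonal Gaussian
# over the latent z_t (this is the network used at forecast time); an
# *inference* encoder d_q that additionally sees the current activity x_t
# and is used during training and reconstruction; and a decoder d_x
# mapping (z_t, h_t) to predicted activity.  Training maximizes the
# per-step ELBO (Gaussian reconstruction log-likelihood minus the KL
# between posterior and conditional prior) summed over bins.
#
# Forecast mode feeds its own predictions forward from the cutoff bin
# (latents from the prior); reconstruct mode is teacher-forced at every
# step (latents from the posterior) and serves as a quality upper bound.

SOFTPLUS_EPS <- 1e-4

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Fixed random stimulus tag table
#'
#' One frozen 50-dimensional vector per stimulus, entries Uniform(-1, 1).
#' Tags identify stimuli to the forecaster; they never change during
#' training.
#'
#' @param stim a [stimulus_set()].
#' @param dim tag dimension (default 50).
#' @param seed RNG seed.
#' @return matrix `n_items x dim`, class `stimulus_tags`.
#' @export
stimulus_tags <- function(stim, dim = 50, seed = 1) {
  n <- length(stim$items)
  tg <- with_seed(derive_seed(seed, "tags"),
                  matrix(runif(n * dim, -1, 1), n, dim))
  rownames(tg) <- stim$items
  structure(tg, class = c("stimulus_tags", "matrix"))
}

#' Per-bin tag inputs for a set of trials
#'
#' The recurrence at step `t` receives the tag active at bin `t-1`:
#' the first-viewed stimulus' tag for bins before second-target viewing,
#' and the vector sum of both stimulus tags afterwards.  A NOSTIM model
#' receives zero tags throughout.
#'
#' @param behavior behavior table (needs `stim_first`, `stim_second`).
#' @param tags a [stimulus_tags()] table, or `NULL` for NOSTIM.
#' @param config a [simulator_config()] (for the bin grid).
#' @param trials which trials (default all).
#' @return array `[tag_dim x n_bins x n_trials]`, entry `[, t, ]` being
#'   `s_{t-1}`.
#' @export
tag_inputs <- function(behavior, tags, config, trials = NULL) {
  trials <- trials %||% seq_len(nrow(behavior))
  Tb <- config$n_bins
  dimtag <- if (is.null(tags)) 50L else ncol(tags)
  out <- array(0, c(dimtag, Tb, length(trials)))
  if (is.null(tags)) return(out)
  tc <- bin_centers(config)
  # bin t-1 for t = 1..Tb; "bin 0" precedes the window (first tag only)
  prev_pre <- c(TRUE, tc[-Tb] < 0)
  for (j in seq_along(trials)) {
    i <- trials[j]
    if (!as.character(behavior$stim_first[i]) %in% rownames(tags))
      stop("missing tag for stimulus ", behavior$stim_first[i])
    t1 <- tags[as.character(behavior$stim_first[i]), ]
    t2 <- tags[as.character(behavior$stim_second[i]), ]
    out[, prev_pre, j] <- t1
    out[, !prev_pre, j] <- t1 + t2
  }
  out
}

#' Initialize forecaster parameters
#'
#' @param n_cells cells (output dimension).
#' @param tag_dim stimulus-tag dimension (50).
#' @param hidden recurrent hidden size (default 64).
#' @param latent latent dimension (default 64).
#' @param enc_hidden hidden width of the prior/posterior/decoder MLPs.
#' @param seed RNG seed.
#' @return named parameter list, class `srnn`.
#' @export
srnn_init <- function(n_cells, tag_dim = 50, hidden = 64, latent = 64,
                      enc_hidden = 64, seed = 1) {
  p <- with_seed(derive_seed(seed, "srnn"), {
    list(W_ih = glorot(n_cells + tag_dim, hidden),
         W_hh = glorot(hidden, hidden),
         b_h = numeric(hidden),
         log_sigma_x = 0)
  })
  prior <- mlp_init(c(latent + hidden, enc_hidden, 2 * latent),
                    seed = derive_seed(seed, "prior"))
  post <- mlp_init(c(latent + hidden + n_cells, enc_hidden, 2 * latent),
                   seed = derive_seed(seed, "post"))
  dec <- mlp_init(c(latent + hidden, enc_hidden, n_cells),
                  seed = derive_seed(seed, "dec"))
  for (nm in names(prior)) p[[paste0("prior_", nm)]] <- prior[[nm]]
  for (nm in names(post)) p[[paste0("post_", nm)]] <- post[[nm]]
  for (nm in names(dec)) p[[paste0("dec_", nm)]] <- dec[[nm]]
  attr(p, "config") <- list(n_cells = n_cells, tag_dim = tag_dim,
                            hidden = hidden, latent = latent,
                            enc_hidden = enc_hidden)
  class(p) <- "srnn"
  p
}

srnn_sub <- function(p, prefix) {
  nms <- grep(paste0("^", prefix, "_"), names(p), value = TRUE)
  sub <- p[nms]
  names(sub) <- sub(paste0(prefix, "_"), "", nms)
  attr(sub, "n_layers") <- 2L
  sub
}

# split a (mu, sigma_raw) MLP output
split_musig <- function(out, latent) {
  list(mu = out[, seq_len(latent), drop = FALSE],
       sraw = out[, latent + seq_len(latent), drop = FALSE])
}

#' Teacher-forced forward pass with ELBO loss (training objective)
#'
#' @param p forecaster parameters.
#' @param X scaled activity `[cells x bins x trials]`.
#' @param S tag inputs from [tag_inputs()].
#' @param eps optional pre-drawn standard-normal array
#'   `[trials x latent x bins]` (reparameterization noise); `NULL` uses the
#'   posterior mean (deterministic).
#' @return list with `loss` (mean negative ELBO per trial), `recon`, `kl`
#'   (per-step sums), `xhat`, and caches for the backward pass.
#' @keywords internal
srnn_forward <- function(p, X, S, eps = NULL) {
  cfg <- attr(p, "config")
  C <- cfg$n_cells; Zd <- cfg$latent; Hd <- cfg$hidden
  X <- as_trial_array(X)
  Tb <- dim(X)[2]; B <- dim(X)[3]
  prior <- srnn_sub(p, "prior"); post <- srnn_sub(p, "post")
  dec <- srnn_sub(p, "dec")
  sx <- exp(p$log_sigma_x)
  h <- matrix(0, B, Hd); z <- matrix(0, B, Zd)
  cache <- vector("list", Tb)
  recon <- kl <- numeric(Tb)
  xhat <- array(0, dim(X))
  for (t in seq_len(Tb)) {
    xprev <- if (t == 1) matrix(0, B, C) else t(X[, t - 1, , drop = FALSE][, 1, ])
    if (B == 1) xprev <- if (t == 1) matrix(0, 1, C) else matrix(X[, t - 1, 1], 1)
    st <- t(matrix(S[, t, ], dim(S)[1], B))
    inp <- cbind(xprev, st)
    hprev <- h
    a <- inp %*% p$W_ih + hprev %*% p$W_hh +
      matrix(p$b_h, B, Hd, byrow = TRUE)
    h <- tanh(a)
    xt <- if (B == 1) matrix(X[, t, 1], 1) else t(X[, t, , drop = FALSE][, 1, ])
    zprev <- z
    pf <- mlp_forward(prior, cbind(zprev, h))
    ms_p <- split_musig(pf$out, Zd)
    sig_p <- softplus(ms_p$sraw) + SOFTPLUS_EPS
    qf <- mlp_forward(post, cbind(zprev, h, xt))
    ms_q <- split_musig(qf$out, Zd)
    sig_q <- softplus(ms_q$sraw) + SOFTPLUS_EPS
    e_t <- if (is.null(eps)) matrix(0, B, Zd) else matrix(eps[, , t], B, Zd)
    z <- ms_q$mu + sig_q * e_t
    df <- mlp_forward(dec, cbind(z, h))
    xh <- df$out
    xhat[, t, ] <- t(xh)
    recon[t] <- 0.5 * sum(((xt - xh) / sx)^2 + 2 * p$log_sigma_x +
                            log(2 * pi)) / B
    kl[t] <- sum(log(sig_p) - log(sig_q) +
                   (sig_q^2 + (ms_q$mu - ms_p$mu)^2) / (2 * sig_p^2) - 0.5) / B
    cache[[t]] <- list(inp = inp, hprev = hprev, h = h, zprev = zprev,
                       xt = xt, xh = xh, pf = pf, qf = qf, df = df,
                       ms_p = ms_p, ms_q = ms_q, sig_p = sig_p,
                       sig_q = sig_q, e = e_t)
  }
  list(loss = sum(recon) + sum(kl), recon = recon, kl = kl,
       xhat = xhat, cache = cache)
}

# backward pass for srnn_forward; returns grads named like p, already
# normalized per trial (loss is mean over the batch)
srnn_backward <- function(p, fw) {
  cfg <- attr(p, "config")
  C <- cfg$n_cells; Zd <- cfg$latent; Hd <- cfg$hidden
  prior <- srnn_sub(p, "prior"); post <- srnn_sub(p, "post")
  dec <- srnn_sub(p, "dec")
  Tb <- length(fw$cache)
  B <- nrow(fw$cache[[1]]$h)
  sx2 <- exp(2 * p$log_sigma_x)
  g <- lapply(p, function(x) x * 0)
  gp <- lapply(prior, function(x) x * 0)
  gq <- lapply(post, function(x) x * 0)
  gd <- lapply(dec, function(x) x * 0)
  dh_next <- matrix(0, B, Hd)
  dz_next <- matrix(0, B, Zd)
  dlsx <- 0
  for (t in rev(seq_len(Tb))) {
    cc <- fw$cache[[t]]
    dxh <- (cc$xh - cc$xt) / sx2
    dlsx <- dlsx + sum(1 - ((cc$xt - cc$xh)^2 / sx2))
    db <- mlp_backward(dec, cc$df$cache, dxh)
    for (nm in names(gd)) gd[[nm]] <- gd[[nm]] + db$grads[[nm]]
    dz <- db$dX[, seq_len(Zd), drop = FALSE] + dz_next
    dh <- db$dX[, Zd + seq_len(Hd), drop = FALSE] + dh_next
    # KL terms
    dd <- cc$ms_q$mu - cc$ms_p$mu
    dmu_q <- dd / cc$sig_p^2
    dmu_p <- -dmu_q
    dsig_q <- cc$sig_q / cc$sig_p^2 - 1 / cc$sig_q
    dsig_p <- 1 / cc$sig_p - (cc$sig_q^2 + dd^2) / cc$sig_p^3
    # reparameterization
    dmu_q <- dmu_q + dz
    dsig_q <- dsig_q + dz * cc$e
    dsq <- dsig_q * sigmoid(cc$ms_q$sraw)
    dsp <- dsig_p * sigmoid(cc$ms_p$sraw)
    qb <- mlp_backward(post, cc$qf$cache, cbind(dmu_q, dsq))
    for (nm in names(gq)) gq[[nm]] <- gq[[nm]] + qb$grads[[nm]]
    pb <- mlp_backward(prior, cc$pf$cache, cbind(dmu_p, dsp))
    for (nm in names(gp)) gp[[nm]] <- gp[[nm]] + pb$grads[[nm]]
    dz_next <- qb$dX[, seq_len(Zd), drop = FALSE] +
      pb$dX[, seq_len(Zd), drop = FALSE]
    dh <- dh + qb$dX[, Zd + seq_len(Hd), drop = FALSE] +
      pb$dX[, Zd + seq_len(Hd), drop = FALSE]
    da <- dh * (1 - cc$h^2)
    g$W_ih <- g$W_ih + t(cc$inp) %*% da
    g$W_hh <- g$W_hh + t(cc$hprev) %*% da
    g$b_h <- g$b_h + colSums(da)
    dh_next <- da %*% t(p$W_hh)
  }
  g$log_sigma_x <- dlsx
  for (nm in names(gp)) g[[paste0("prior_", nm)]] <- gp[[nm]]
  for (nm in names(gq)) g[[paste0("post_", nm)]] <- gq[[nm]]
  for (nm in names(gd)) g[[paste0("dec_", nm)]] <- gd[[nm]]
  lapply(g, function(x) x / B)
}

#' One generative forecaster step (prior path)
#'
#' @param p forecaster parameters.
#' @param x_prev previous activity (vector or `trials x cells`).
#' @param s_prev stimulus tag at the previous bin (zero vector in NOSTIM
#'   mode).
#' @param h_prev,z_prev recurrent and latent state (`NULL` = zero state).
#' @param mode `"mean"` (deterministic) or `"sample"` (draw z from the
#'   conditional prior; uses the caller's RNG).
#' @return list `x` (predicted activity), `h`, `z`, `sig` (prior sd, always
#'   positive).
#' @export
forecaster_step <- function(p, x_prev, s_prev, h_prev = NULL, z_prev = NULL,
                            mode = c("mean", "sample")) {
  mode <- match.arg(mode)
  cfg <- attr(p, "config")
  if (is.null(dim(x_prev))) x_prev <- matrix(x_prev, 1)
  if (is.null(dim(s_prev))) s_prev <- matrix(s_prev, 1)
  B <- nrow(x_prev)
  h_prev <- h_prev %||% matrix(0, B, cfg$hidden)
  z_prev <- z_prev %||% matrix(0, B, cfg$latent)
  h <- tanh(cbind(x_prev, s_prev) %*% p$W_ih + h_prev %*% p$W_hh +
              matrix(p$b_h, B, cfg$hidden, byrow = TRUE))
  pf <- mlp_forward(srnn_sub(p, "prior"), cbind(z_prev, h))
  ms <- split_musig(pf$out, cfg$latent)
  sig <- softplus(ms$sraw) + SOFTPLUS_EPS
  z <- if (mode == "sample") ms$mu + sig * matrix(rnorm(length(sig)), B)
  else ms$mu
  x <- mlp_forward(srnn_sub(p, "dec"), cbind(z, h))$out
  list(x = x, h = h, z = z, sig = sig)
}

#' Forecast or reconstruct the bins beyond a cutoff
#'
#' Forecast mode runs teacher-forced (posterior mean) through the real
#' prefix `1..cutoff`, then feeds its own predictions forward using the
#' conditional prior; reconstruct mode is teacher-forced at every step.
#' Both return predictions for bins `cutoff+1 .. n_bins` together with the
#' complementary attention-mask pair that routes them in the combined
#' agent.
#'
#' @param p forecaster parameters.
#' @param x one trial, `cells x bins`.
#' @param s tag inputs for the trial (`tag_dim x bins`, entry t being
#'   `s_{t-1}`).
#' @param cutoff last real bin (1..n_bins); `cutoff = n_bins` yields an
#'   empty (degenerate) forecast.
#' @param mode `"forecast"` or `"reconstruct"`.
#' @return list: `pred` (`cells x (n_bins - cutoff)`), `bins` (forecasted
#'   bin indices), `core_mask`, `forecast_mask`.
#' @export
forecast_rollout <- function(p, x, s, cutoff,
                             mode = c("forecast", "reconstruct")) {
  mode <- match.arg(mode)
  Tb <- ncol(x)
  if (cutoff < 1 || cutoff > Tb) stop("cutoff out of range")
  filled <- forecast_fill(p, array(x, c(nrow(x), Tb, 1)),
                          array(s, c(nrow(s), Tb, 1)), cutoff, mode)
  bins <- if (cutoff < Tb) (cutoff + 1):Tb else integer(0)
  list(pred = filled[, bins, 1, drop = TRUE],
       bins = bins,
       core_mask = as.integer(seq_len(Tb) <= cutoff),
       forecast_mask = as.integer(seq_len(Tb) > cutoff))
}

#' Standardization statistics for forecast-path inputs
#'
#' Forecasted activity is dominated by static per-(cell, bin) mean
#' patterns; the choice-relevant signal is the small trial-to-trial
#' variation around them.  The forecast path therefore standardizes its
#' input per (cell, bin) -- the same convention the preprocessing applies
#' to real data -- using statistics from training-trial forecasts.
#'
#' @param ff training-trial forecast tensor `[cells x bins x trials]`.
#' @return list `mu`, `sd` (degenerate features get sd 1 and stay 0).
#' @export
forecast_stats <- function(ff) {
  mu <- apply(ff, c(1, 2), mean)
  sdv <- apply(ff, c(1, 2), sd)
  dead <- sdv < 1e-8
  mu[dead] <- 0
  sdv[dead] <- 1
  list(mu = mu, sd = sdv)
}

#' @rdname forecast_stats
#' @param stats from [forecast_stats()].
#' @param scale target per-feature standard deviation (0.5 keeps the
#'   result well inside the `[-1, 1]` data range).
#' @export
forecast_standardize <- function(ff, stats, scale = 0.5) {
  out <- sweep(sweep(ff, c(1, 2), stats$mu, "-"), c(1, 2), stats$sd, "/") *
    scale
  pmin(pmax(out, -1), 1)
}

#' Batched forecast of post-cutoff bins for many trials
#'
#' @param p forecaster parameters.
#' @param X `[cells x bins x trials]` scaled activity.
#' @param S tag inputs (see [tag_inputs()]).
#' @param cutoffs scalar or per-trial vector of cutoffs.
#' @param mode `"forecast"` (self-fed after the cutoff) or `"reconstruct"`
#'   (teacher-forced throughout).
#' @return `[cells x bins x trials]` array: forecasted bins filled,
#'   real-prefix bins zero.
#' @export
forecast_fill <- function(p, X, S, cutoffs,
                          mode = c("forecast", "reconstruct")) {
  mode <- match.arg(mode)
  cfg <- attr(p, "config")
  X <- as_trial_array(X)
  C <- dim(X)[1]; Tb <- dim(X)[2]; B <- dim(X)[3]
  cutoffs <- rep_len(as.integer(cutoffs), B)
  c_eff <- if (mode == "reconstruct") rep(Tb, B) else cutoffs
  prior <- srnn_sub(p, "prior"); post <- srnn_sub(p, "post")
  dec <- srnn_sub(p, "dec")
  h <- matrix(0, B, cfg$hidden); z <- matrix(0, B, cfg$latent)
  xpred_prev <- matrix(0, B, C)     # model's own prediction of bin t-1
  out <- array(0, dim(X))
  for (t in seq_len(Tb)) {
    xreal_prev <- if (t == 1) matrix(0, B, C) else
      matrix(aperm(X[, t - 1, , drop = FALSE], c(3, 1, 2)), B, C)
    use_real <- (t - 1) <= c_eff
    xin <- xreal_prev
    if (any(!use_real)) xin[!use_real, ] <- xpred_prev[!use_real, ]
    st <- matrix(aperm(S[, t, , drop = FALSE], c(3, 1, 2)), B)
    h <- tanh(cbind(xin, st) %*% p$W_ih + h %*% p$W_hh +
                matrix(p$b_h, B, cfg$hidden, byrow = TRUE))
    xt <- matrix(aperm(X[, t, , drop = FALSE], c(3, 1, 2)), B, C)
    use_post <- t <= c_eff
    zp <- split_musig(mlp_forward(prior, cbind(z, h))$out, cfg$latent)$mu
    zq <- split_musig(mlp_forward(post, cbind(z, h, xt))$out, cfg$latent)$mu
    z <- zp
    if (any(use_post)) z[use_post, ] <- zq[use_post, , drop = FALSE]
    xh <- mlp_forward(dec, cbind(z, h))$out
    xpred_prev <- xh
    fill <- t > cutoffs
    if (any(fill)) out[, t, fill] <- t(xh[fill, , drop = FALSE])
  }
  out
}
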