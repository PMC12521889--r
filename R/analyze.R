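# Interrogating trained agents: how much value information their
# representations carry, which time bins drive their Q values, and how
# accuracy depends on trial difficulty and on the available data prefix.

# out-of-sample R^2 (1 - SS_res / SS_tot around the held-out mean)
oos_r2 <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / sst
}

ols_fit_predict <- function(Xtr, ytr, Xte) {
  fit <- stats::lm.fit(cbind(1, Xtr), ytr)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  drop(cbind(1, Xte) %*% beta)
}

#' Decode stimulus values from the agent's internal representations
#'
#' Extracts the class-token vector for every trial, fits ordinary least
#' squares on the training-trial representations, and reports out-of-sample
#' R^2 on the held-out trials for the first-viewed value, second-viewed
#' value and their difference.
#'
#' @param agent a trained `core_agent`.
#' @param scaled `trials x cells x bins` scaled session.
#' @param behavior the session behavior table.
#' @param split a `split_spec`.
#' @return data frame with `target` and `r2`.
#' @export
decode_values_from_representations <- function(agent, scaled, behavior,
                                               split) {
  X <- aperm(scaled, c(2, 3, 1))
  chi <- core_forward(agent, X)$chi
  targets <- list(value_first = behavior$value_first,
                  value_second = behavior$value_second,
                  value_difference = behavior$value_first -
                    behavior$value_second)
  r2 <- vapply(targets, function(y) {
    pred <- ols_fit_predict(chi[split$train, , drop = FALSE], y[split$train],
                            chi[split$test, , drop = FALSE])
    oos_r2(y[split$test], pred)
  }, 0)
  data.frame(target = names(targets), r2 = unname(r2))
}

#' Time-resolved linear value decoding from raw activity
#'
#' Per time bin, cross-validated R^2 of OLS decoding of the first- and
#' second-viewed stimulus values from that bin's population vector
#' (k-fold CV with repeats; R^2 pooled over folds per repeat, averaged
#' over repeats).
#'
#' @param spikes `trials x cells x bins` counts (raw or scaled).
#' @param behavior behavior table.
#' @param folds,repeats CV scheme (defaults 5 x 10).
#' @param seed RNG seed for fold assignment.
#' @return data frame: `bin`, `target`, `r2`.
#' @export
timecourse_value_decoding <- function(spikes, behavior, folds = 5,
                                      repeats = 10, seed = 1) {
  n <- dim(spikes)[1]; Tb <- dim(spikes)[3]
  if (n < folds) stop("fewer trials than folds")
  targets <- list(value_first = behavior$value_first,
                  value_second = behavior$value_second)
  out <- expand.grid(bin = seq_len(Tb), target = names(targets),
                     stringsAsFactors = FALSE)
  out$r2 <- NA_real_
  for (tb in seq_len(Tb)) {
    Xb <- spikes[, , tb]
    for (tg in names(targets)) {
      y <- targets[[tg]]
      r2r <- numeric(repeats)
      for (rep_i in seq_len(repeats)) {
        fold <- with_seed(derive_seed(seed, "cv", tb, tg, rep_i),
                          sample(rep_len(seq_len(folds), n)))
        yhat <- numeric(n)
        for (f in seq_len(folds)) {
          te <- fold == f
          yhat[te] <- ols_fit_predict(Xb[!te, , drop = FALSE], y[!te],
                                      Xb[te, , drop = FALSE])
        }
        r2r[rep_i] <- oos_r2(y, yhat)
      }
      out$r2[out$bin == tb & out$target == tg] <- mean(r2r)
    }
  }
  out
}

#' Expected-gradients Shapley approximation
#'
#' Gradient-based Shapley estimator: attribution of feature `i` is
#' `E[(x_i - b_i) * df/dx_i(b + a (x - b))]` over background points `b`
#' and interpolation coefficients `a ~ Uniform(0, 1)`.  Exact for linear
#' models in expectation; agreement with exhaustive-coalition Shapley on
#' small models is enforced in the test suite.
#'
#' @param grad_fn function taking an input array shaped like `X` and
#'   returning the gradient of the explained scalar output w.r.t. each
#'   entry (same shape).
#' @param X inputs to explain, `[... x trials]` (trial index last).
#' @param background background inputs, same feature shape.
#' @param n_samples background/interpolation draws per trial.
#' @param seed RNG seed.
#' @return attribution array shaped like `X`.
#' @export
shapley_expected_gradients <- function(grad_fn, X, background,
                                       n_samples = 50, seed = 1) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  d <- dim(X); B <- d[length(d)]
  nb <- dim(background)[length(d)]
  Xm <- matrix(X, ncol = B)
  Bg <- matrix(background, ncol = nb)
  acc <- matrix(0, nrow(Xm), B)
  with_seed(derive_seed(seed, "eg"), {
    for (s in seq_len(n_samples)) {
      bi <- sample(nb, B, replace = TRUE)
      al <- runif(B)
      Xt <- Bg[, bi, drop = FALSE] +
        (Xm - Bg[, bi, drop = FALSE]) * rep(al, each = nrow(Xm))
      G <- matrix(grad_fn(array(Xt, d)), ncol = B)
      acc <- acc + (Xm - Bg[, bi, drop = FALSE]) * G
    }
  })
  array(acc / n_samples, d)
}

#' Temporal Shapley attribution of an agent's Q values
#'
#' Explains the Q value of the greedy (chosen) action on held-out trials
#' with [shapley_expected_gradients()], against a background of training
#' trials.  Absolute attributions are averaged over cells and trials and
#' normalized to sum to 1 over bins.
#'
#' @param agent trained `core_agent`.
#' @param X_test held-out scaled trials `[cells x bins x trials]`.
#' @param background background trials `[cells x bins x m]` (training
#'   trials; default sample size 50 upstream).
#' @param n_samples draws per trial.
#' @param seed RNG seed.
#' @return list: `per_bin` (normalized, sums to 1), `raw`
#'   (`cells x bins x trials` signed attributions).
#' @export
shapley_time_attribution <- function(agent, X_test, background,
                                     n_samples = 50, seed = 1) {
  X_test <- as_trial_array(X_test)
  fw0 <- core_forward(agent, X_test)
  act <- max.col(fw0$q, ties.method = "first")
  grad_fn <- function(Xa) {
    B <- dim(Xa)[3]
    fw <- core_forward(agent, Xa)
    dq <- matrix(0, B, ncol(fw$q))
    dq[cbind(seq_len(B), act)] <- 1
    core_backward(agent, Xa, dq, fw = fw, want_dx = TRUE)$dX
  }
  raw <- shapley_expected_gradients(grad_fn, X_test, background,
                                    n_samples, seed)
  per_bin <- apply(abs(raw), 2, mean)
  list(per_bin = per_bin / sum(per_bin), raw = raw)
}

#' Accuracy by absolute value difference
#'
#' @param behavior behavior table for the evaluated trials.
#' @param predicted predicted choices (1/2) for the same trials.
#' @return data frame: `delta` (0..4), `accuracy` (NA when the condition
#'   is empty), `n`.
#' @export
accuracy_by_value_difference <- function(behavior, predicted) {
  delta <- abs(behavior$value_first - behavior$value_second)
  ok <- predicted == behavior$choice
  out <- data.frame(delta = 0:4, accuracy = NA_real_, n = 0L)
  for (d in 0:4) {
    sel <- delta == d
    out$n[out$delta == d] <- sum(sel)
    if (any(sel)) out$accuracy[out$delta == d] <- mean(ok[sel])
  }
  out
}

#' Held-out accuracy versus cutoff for masked-environment agents
#'
#' Evaluates the BASE agent and the STIM/NOSTIM combined agents (plus
#' their path ablations) at every fixed cutoff.
#'
#' @param agents named list; recognized names: `BASE` (core agent),
#'   `STIM`, `NOSTIM` (combined agents).
#' @param X_test held-out scaled trials `[cells x bins x trials]`.
#' @param choice held-out choices.
#' @param tags_in_test tag inputs for the held-out trials (STIM path).
#' @param cutoffs cutoffs to evaluate (default all bins).
#' @param cases restrict to these case labels (default: all available).
#' @return data frame: `case`, `cutoff`, `accuracy`.
#' @export
ablation_cutoff_curves <- function(agents, X_test, choice,
                                   tags_in_test = NULL, cutoffs = NULL,
                                   cases = NULL) {
  wanted <- cases
  X_test <- as_trial_array(X_test)
  Tb <- dim(X_test)[2]
  cutoffs <- cutoffs %||% seq_len(Tb)
  zt <- array(0, dim(tags_in_test %||% array(0, c(50, Tb, dim(X_test)[3]))))
  case_fns <- list()
  if (!is.null(agents$BASE))
    case_fns$BASE <- function(ct) evaluate_agent(agents$BASE, X_test, choice, ct)
  if (!is.null(agents$STIM)) {
    case_fns$STIM <- function(ct) evaluate_agent(agents$STIM, X_test, choice, ct,
                                              tags_in_test)
    case_fns$`S-NOBASE` <- function(ct) evaluate_agent(agents$STIM, X_test,
      choice, ct, tags_in_test, ablation = "no_core")
    case_fns$`S-NOINT` <- function(ct) evaluate_agent(agents$STIM, X_test,
      choice, ct, tags_in_test, ablation = "no_forecast")
    case_fns$`S-NOSV` <- function(ct) evaluate_agent(agents$STIM, X_test,
      choice, ct, tags_in_test, zero_tags = TRUE)
  }
  if (!is.null(agents$NOSTIM)) {
    case_fns$NOSTIM <- function(ct) evaluate_agent(agents$NOSTIM, X_test, choice,
                                                ct, zt)
    case_fns$`NS-NOBASE` <- function(ct) evaluate_agent(agents$NOSTIM, X_test,
      choice, ct, zt, ablation = "no_core")
    case_fns$`NS-NOINT` <- function(ct) evaluate_agent(agents$NOSTIM, X_test,
      choice, ct, zt, ablation = "no_forecast")
  }
  if (!is.null(wanted))
    case_fns <- case_fns[intersect(names(case_fns), wanted)]
  out <- expand.grid(case = names(case_fns), cutoff = cutoffs,
                     stringsAsFactors = FALSE)
  out$accuracy <- NA_real_
  for (i in seq_len(nrow(out)))
    out$accuracy[i] <- case_fns[[out$case[i]]](out$cutoff[i])$accuracy
  out
}

#' Earliest cutoff time at which an accuracy curve reaches a criterion
#'
#' @param curve data frame with `cutoff` and `accuracy` (one case).
#' @param criterion accuracy criterion.
#' @param config a [simulator_config()] (for the bin grid); cutoff time is
#'   the end of the last real bin, in seconds.
#' @return cutoff time in seconds (`NA` if never reached).
#' @export
criterion_crossing_time <- function(curve, criterion, config) {
  curve <- curve[order(curve$cutoff), ]
  hit <- which(curve$accuracy >= criterion)
  if (!length(hit)) return(NA_real_)
  config$window_start + curve$cutoff[hit[1]] * config$bin_width
}
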