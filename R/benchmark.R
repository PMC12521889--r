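# Supervised baselines and uncertainty decomposition.
#
# The kernel baseline is a radial-basis-function kernel classifier fit by
# penalized logistic regression (IRLS).  The reference implementation in
# the Python ecosystem is an RBF support-vector classifier; no kernel SVM
# is available in this R stack, and the uncertainty analysis needs
# calibrated probabilities anyway, so kernel logistic regression is used
# as the calibrated RBF-kernel classifier.  The recurrent baseline is a
# single-layer tanh RNN (hidden size 100) whose last hidden state feeds a
# linear classifier.

#' Fit an RBF-kernel logistic classifier
#'
#' @param X `n x p` feature matrix (flattened cells x bins vectors).
#' @param y labels in `{1, 2}`.
#' @param gamma RBF width; default `1 / (p * var(X))` (the usual "scale"
#'   heuristic).
#' @param lambda ridge penalty on the dual coefficients.
#' @param iters IRLS iterations.
#' @return object of class `kernel_rbf`.
#' @export
kernel_rbf_fit <- function(X, y, gamma = NULL, lambda = 1e-2, iters = 25) {
  y01 <- as.numeric(y == 2)
  if (length(unique(y01)) < 2) stop("training labels contain a single class")
  gamma <- gamma %||% (1 / (ncol(X) * max(mean(apply(X, 2, var)), 1e-12)))
  K <- rbf_gram(X, X, gamma)
  n <- nrow(X)
  alpha <- numeric(n)
  for (it in seq_len(iters)) {
    f <- drop(K %*% alpha)
    p <- 1 / (1 + exp(-f))
    W <- pmax(p * (1 - p), 1e-6)
    # Newton step on the penalized deviance (K-space parameterization)
    delta <- solve(K * W + diag(lambda, n), (p - y01) + lambda * alpha)
    alpha <- alpha - delta
    if (max(abs(delta)) < 1e-8) break
  }
  structure(list(alpha = alpha, X = X, gamma = gamma, lambda = lambda),
            class = "kernel_rbf")
}

rbf_gram <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

#' @describeIn kernel_rbf_fit predicted probabilities (`n x 2`, columns =
#'   classes 1 and 2) for new data.
#' @param object fitted classifier.
#' @param Xnew new feature matrix.
#' @export
kernel_rbf_predict <- function(object, Xnew) {
  f <- drop(rbf_gram(Xnew, object$X, object$gamma) %*% object$alpha)
  p2 <- 1 / (1 + exp(-f))
  cbind(1 - p2, p2)
}

#' Train the recurrent supervised baseline
#'
#' @param X `[cells x bins x trials]` scaled input.
#' @param y labels in `{1, 2}`.
#' @param hidden hidden units (default 100, matched to the Q-decoder's
#'   embedding width).
#' @param epochs,lr,batch_size Adam settings.
#' @param seed RNG seed.
#' @return object of class `rnn_classifier`.
#' @export
rnn_classifier_fit <- function(X, y, hidden = 100, epochs = 80, lr = 1e-3,
                               batch_size = 64, seed = 1) {
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  C <- dim(X)[1]; n <- dim(X)[3]
  p <- rnn_init(C, hidden, 2, seed = derive_seed(seed, "rnn"))
  opt <- adam_init(p)
  Y <- onehot(y, 2)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, "rnn_ep", ep), sample(n))
    for (b0 in seq(1, n, by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1, n)]
      fw <- rnn_forward(p, X[, , bi, drop = FALSE])
      pr <- softmax_rows(fw$out)
      dout <- (pr - Y[bi, , drop = FALSE]) / length(bi)
      g <- rnn_backward(p, fw, dout)
      up <- adam_step(p, g, opt, lr = lr)
      p <- up$params; opt <- up$state
    }
  }
  structure(list(params = p), class = "rnn_classifier")
}

#' @describeIn rnn_classifier_fit predicted class probabilities.
#' @param object fitted classifier.
#' @param Xnew `[cells x bins x trials]`.
#' @export
rnn_classifier_predict <- function(object, Xnew) {
  softmax_rows(rnn_forward(object$params, Xnew)$out)
}

#' Train and evaluate the supervised baselines
#'
#' Fits the RBF-kernel classifier (on flattened cells x bins vectors) and
#' the recurrent network on the scaled session, with supervised choice
#' labels, no augmentation and full-length trials.  Accuracy is the mean
#' over `folds`-fold CV test splits.
#'
#' @param scaled `trials x cells x bins` scaled session.
#' @param choice labels (1/2).
#' @param folds CV folds (default 5).
#' @param seed RNG seed.
#' @param rnn_epochs training epochs for the recurrent baseline.
#' @return list: `accuracy` (named: kernel, rnn), `per_fold`, and the
#'   models from the last fold.
#' @export
train_supervised_baselines <- function(scaled, choice, folds = 5, seed = 1,
                                       rnn_epochs = 60) {
  n <- dim(scaled)[1]
  Xf <- matrix(scaled, n)                   # n x (cells*bins)
  Xa <- aperm(scaled, c(2, 3, 1))
  fold <- with_seed(derive_seed(seed, "folds"),
                    sample(rep_len(seq_len(folds), n)))
  acc <- matrix(NA_real_, folds, 2, dimnames = list(NULL, c("kernel", "rnn")))
  for (f in seq_len(folds)) {
    te <- fold == f
    km <- kernel_rbf_fit(Xf[!te, , drop = FALSE], choice[!te])
    kp <- kernel_rbf_predict(km, Xf[te, , drop = FALSE])
    acc[f, "kernel"] <- mean(max.col(kp) == choice[te])
    rm_ <- rnn_classifier_fit(Xa[, , !te, drop = FALSE], choice[!te],
                              epochs = rnn_epochs,
                              seed = derive_seed(seed, "rnnfold", f))
    rp <- rnn_classifier_predict(rm_, Xa[, , te, drop = FALSE])
    acc[f, "rnn"] <- mean(max.col(rp) == choice[te])
  }
  list(accuracy = colMeans(acc), per_fold = acc,
       kernel_model = km, rnn_model = rm_)
}

#' Truncated-input evaluation by suffix permutation
#'
#' For decoders that require full-length input, accuracy at cutoff `c` is
#' estimated after replacing all post-cutoff bins with the corresponding
#' bins of randomly permuted trials (`n_permutations` draws, accuracy
#' averaged).  At `cutoff = n_bins` nothing is permuted and the
#' untruncated accuracy is returned exactly.
#'
#' @param predict_fn function mapping `[cells x bins x trials]` to an
#'   `n x 2` probability matrix.
#' @param X `[cells x bins x trials]` evaluation trials.
#' @param y labels (1/2).
#' @param cutoffs cutoffs to evaluate.
#' @param n_permutations permutation draws per cutoff.
#' @param seed RNG seed.
#' @return data frame: `cutoff`, `accuracy`.
#' @export
truncated_input_evaluation <- function(predict_fn, X, y, cutoffs,
                                       n_permutations = 1000, seed = 1) {
  X <- as_trial_array(X)
  Tb <- dim(X)[2]; n <- dim(X)[3]
  if (any(cutoffs < 1 | cutoffs > Tb)) stop("cutoff outside bin range")
  out <- data.frame(cutoff = cutoffs, accuracy = NA_real_)
  for (j in seq_along(cutoffs)) {
    ct <- cutoffs[j]
    if (ct == Tb) {
      out$accuracy[j] <- mean(max.col(predict_fn(X)) == y)
      next
    }
    accs <- with_seed(derive_seed(seed, "perm", ct), {
      vapply(seq_len(n_permutations), function(k) {
        perm <- sample(n)
        Xp <- X
        Xp[, (ct + 1):Tb, ] <- X[, (ct + 1):Tb, perm]
        mean(max.col(predict_fn(Xp)) == y)
      }, 0)
    })
    out$accuracy[j] <- mean(accs)
  }
  out
}

#' Ensemble uncertainty decomposition
#'
#' Total uncertainty is the entropy of the member-averaged predictive
#' distribution, aleatoric uncertainty the mean member entropy, and
#' epistemic uncertainty their difference (all natural-log entropies):
#' `TU = H[mean_i p_i]`, `AU = mean_i H[p_i]`, `EU = TU - AU >= 0`.
#'
#' @param probs array `[members x trials x classes]`; each member row must
#'   be a probability distribution.
#' @return object of class `uncertainty_report`: per-trial `TU`, `AU`,
#'   `EU`, the session means, and the ensemble prediction (argmax of the
#'   member-averaged probabilities).
#' @export
ensemble_uncertainty <- function(probs) {
  stopifnot(length(dim(probs)) == 3)
  if (any(probs < -1e-9 | probs > 1 + 1e-9))
    stop("probabilities outside [0, 1]")
  sums <- apply(probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) stop("member probabilities not normalized")
  pbar <- apply(probs, c(2, 3), mean)
  tu <- entropy_nats(pbar)
  member_h <- apply(probs, c(1, 2), entropy_nats)   # members x trials
  au <- colMeans(matrix(member_h, dim(probs)[1]))
  eu <- tu - au
  structure(list(TU = tu, AU = au, EU = eu,
                 mean = c(TU = mean(tu), AU = mean(au), EU = mean(eu)),
                 predicted = max.col(pbar)),
            class = "uncertainty_report")
}

#' Train a 5-member decoder ensemble and collect held-out probabilities
#'
#' Neural decoders (RL agent, recurrent net) are diversified by random
#' initialization; the kernel classifier by fitting each member on a
#' disjoint fifth of the training set.
#'
#' @param scaled `trials x cells x bins` scaled session.
#' @param choice labels (1/2).
#' @param split a `split_spec`.
#' @param family `"rl_agent"`, `"kernel_svc"` or `"rnn"`.
#' @param size ensemble members (default 5).
#' @param seed RNG seed.
#' @param rl_config [train_config()] for RL members.
#' @param rnn_epochs epochs for recurrent members.
#' @param d_model,episode_length RL member architecture/rollout settings.
#' @return list: `probs` (`[size x n_test x 2]`), `accuracy` (ensemble,
#'   via averaged probabilities), `report` ([ensemble_uncertainty()]).
#' @export
train_ensemble <- function(scaled, choice, split,
                           family = c("rl_agent", "kernel_svc", "rnn"),
                           size = 5, seed = 1,
                           rl_config = NULL, rnn_epochs = 40,
                           d_model = 100, episode_length = 128) {
  family <- match.arg(family)
  Xa <- aperm(scaled, c(2, 3, 1))
  tr <- split$train; te <- split$test
  probs <- array(NA_real_, c(size, length(te), 2))
  for (m in seq_len(size)) {
    mseed <- derive_seed(seed, "member", m)
    if (family == "kernel_svc") {
      part <- with_seed(derive_seed(seed, "parts"),
                        sample(rep_len(seq_len(size), length(tr))))
      sub <- tr[part == m]
      km <- kernel_rbf_fit(matrix(scaled[sub, , ], length(sub)), choice[sub])
      probs[m, , ] <- kernel_rbf_predict(km,
                                         matrix(scaled[te, , ], length(te)))
    } else if (family == "rnn") {
      rm_ <- rnn_classifier_fit(Xa[, , tr, drop = FALSE], choice[tr],
                                epochs = rnn_epochs, seed = mseed)
      probs[m, , ] <- rnn_classifier_predict(rm_, Xa[, , te, drop = FALSE])
    } else {
      cfg <- rl_config %||% train_config(n_iterations = 60)
      cfg$seed <- derive_seed(mseed, "rollout")
      env <- env_choice(Xa[, , tr, drop = FALSE], choice[tr],
                        episode_length = episode_length, seed = cfg$seed)
      ag <- core_agent(dim(Xa)[1], dim(Xa)[2], d_model = d_model,
                       seed = mseed)
      tr_out <- train_agent(env, ag, cfg)
      ev <- evaluate_agent(tr_out$agent, Xa[, , te, drop = FALSE], choice[te])
      probs[m, , ] <- ev$p
    }
  }
  rep_ <- ensemble_uncertainty(probs)
  list(probs = probs, accuracy = mean(rep_$predicted == choice[te]),
       report = rep_)
}
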