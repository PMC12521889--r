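test_that("transformer gradients match finite differences", {
  set.seed(42)
  p <- tiny_tf()
  C <- 3; Tb <- 5; B <- 2
  X <- array(runif(C * Tb * B, -1, 1), c(C, Tb, B))
  mask <- matrix(1, B, Tb); mask[1, 4:5] <- 0
  w <- matrix(rnorm(8 * B), B, 8)
  loss <- function(pp) sum(w * tf_forward(pp, X, mask)$chi)
  bk <- tf_backward(p, X, w, mask)
  expect_lt(fd_check(loss, p, bk$grads), 1e-6)
  # input gradients
  worst <- 0
  for (i in sample(length(X), 10)) {
    eps <- 1e-5
    XX <- X; XX[i] <- XX[i] + eps; f1 <- sum(w * tf_forward(p, XX, mask)$chi)
    XX[i] <- XX[i] - 2 * eps; f0 <- sum(w * tf_forward(p, XX, mask)$chi)
    num <- (f1 - f0) / (2 * eps)
    worst <- max(worst, abs(num - bk$dX[i]) / max(1, abs(num) + abs(bk$dX[i])))
  }
  expect_lt(worst, 1e-6)
  # cached-state backward equals recompute backward
  fw <- tf_forward(p, X, mask, want_state = TRUE)
  bs <- tf_backward_state(p, fw$state, w)
  expect_equal(bs$grads, bk$grads)
  expect_equal(bs$dX, bk$dX)
})

test_that("masking is sound: outputs invariant to hidden-bin content,
           attention rows normalize", {
  ag <- core_agent(5, 8, d_model = 16, n_heads = 2, d_ff = 24, seed = 2)
  X <- array(runif(5 * 8 * 4, -1, 1), c(5, 8, 4))
  mask <- matrix(rep(as.integer(seq_len(8) <= 3), each = 4), 4, 8)
  f1 <- core_forward(ag, X, mask, return_attn = TRUE)
  X2 <- X; X2[, 4:8, ] <- rnorm(5 * 5 * 4) * 10
  f2 <- core_forward(ag, X2, mask)
  expect_identical(f1$q, f2$q)
  expect_identical(dim(f1$q), c(4L, 2L))          # one Q per action
  # every post-softmax attention row sums to 1
  A <- f1$attn[[1]][[1]]                           # layer 1, trial 1 cube
  expect_true(all(abs(apply(A, 3, rowSums) - 1) < 1e-12))
})

test_that("Boltzmann policy: softmax values, normalization, invariances", {
  p <- boltzmann_policy(c(1, 0))
  expect_equal(p, c(exp(1) / (1 + exp(1)), 1 / (1 + exp(1))))
  expect_equal(unname(p[1]), 0.7311, tolerance = 1e-4)
  expect_equal(boltzmann_policy(c(3, 3)), c(0.5, 0.5))
  q <- matrix(rnorm(50), 10)
  pm <- boltzmann_policy(q, tau = 0.7)
  expect_true(all(abs(rowSums(pm) - 1) < 1e-12))
  expect_equal(boltzmann_policy(q + 100, tau = 0.7), pm)   # shift invariance
  expect_error(boltzmann_policy(c(1, 0), tau = 0), "tau")
})

test_that("forecaster gradients match finite differences and KL >= 0", {
  set.seed(1)
  C <- 4; Tb <- 6; B <- 3
  p <- srnn_init(C, tag_dim = 5, hidden = 8, latent = 7, enc_hidden = 9,
                 seed = 3)
  X <- array(runif(C * Tb * B, -1, 1), c(C, Tb, B))
  S <- array(runif(5 * Tb * B, -1, 1), c(5, Tb, B))
  eps <- array(rnorm(B * 7 * Tb), c(B, 7, Tb))
  fw <- valdec:::srnn_forward(p, X, S, eps)
  expect_true(all(fw$kl >= 0))
  gr <- valdec:::srnn_backward(p, fw)
  loss <- function(pp) valdec:::srnn_forward(pp, X, S, eps)$loss
  expect_lt(fd_check(loss, p, gr, n_per = 3), 1e-6)
})

test_that("forecaster stepping: determinism, positivity, zero tags", {
  p <- srnn_init(4, tag_dim = 5, hidden = 8, latent = 6, enc_hidden = 8,
                 seed = 4)
  x <- runif(4); s <- runif(5)
  a <- forecaster_step(p, x, s, mode = "mean")
  b <- forecaster_step(p, x, s, mode = "mean")
  expect_identical(a$x, b$x)                       # mean mode deterministic
  expect_true(all(a$sig > 0))                      # positive sd always
  # NOSTIM: tag inputs are all-zero for every stimulus
  s0 <- small_session()
  z <- tag_inputs(s0$behavior, NULL, s0$config)
  expect_true(all(z == 0))
  tg <- stimulus_tags(s0$stimulus_set, seed = 2)
  tin <- tag_inputs(s0$behavior, tg, s0$config, trials = 1:3)
  # before second viewing: first tag; afterwards: vector sum of both
  b1 <- s0$behavior[1, ]
  expect_equal(tin[, 2, 1], unname(tg[as.character(b1$stim_first), ]))
  expect_equal(tin[, 9, 1],
               unname(tg[as.character(b1$stim_first), ] +
                        tg[as.character(b1$stim_second), ]))
})

test_that("forecast rollout: degenerate cutoff and error cases", {
  p <- srnn_init(4, tag_dim = 5, hidden = 8, latent = 6, enc_hidden = 8,
                 seed = 5)
  x <- matrix(runif(4 * 12, -1, 1), 4)
  s <- matrix(0, 5, 12)
  fr <- forecast_rollout(p, x, s, cutoff = 12)
  expect_length(fr$bins, 0)                        # empty forecast is valid
  expect_identical(fr$core_mask, rep(1L, 12))
  expect_error(forecast_rollout(p, x, s, cutoff = 0), "cutoff")
  fr6 <- forecast_rollout(p, x, s, cutoff = 6)
  expect_identical(fr6$bins, 7:12)
  expect_identical(fr6$forecast_mask, as.integer(seq_len(12) > 6))
})

test_that("combined agent: path ablations zero the right representation", {
  p <- srnn_init(5, hidden = 8, latent = 6, enc_hidden = 8, seed = 6)
  ag <- combined_agent(5, 8, p, NULL, d_model = 16, n_heads = 2, d_ff = 24,
                       seed = 7)
  X <- array(runif(5 * 8 * 3, -1, 1), c(5, 8, 3))
  fc <- array(runif(5 * 8 * 3, -1, 1), c(5, 8, 3))
  f0 <- combined_forward(ag, X, 4, fc)
  fnc <- combined_forward(ag, X, 4, fc, ablation = "no_core")
  fnf <- combined_forward(ag, X, 4, fc, ablation = "no_forecast")
  expect_true(all(fnc$chi_core == 0) && all(fnf$chi_fore == 0))
  expect_false(all(f0$chi_core == 0))
  # with a zero-initialized fusion head all ablations agree at Q = 0
  expect_true(all(f0$q == 0))
})

test_that("small mlp and rnn backprop are exact", {
  set.seed(9)
  p <- valdec:::mlp_init(c(4, 6, 3), seed = 1)
  X <- matrix(rnorm(8), 2, 4)
  w <- matrix(rnorm(6), 2, 3)
  fw <- valdec:::mlp_forward(p, X)
  bk <- valdec:::mlp_backward(p, fw$cache, w)
  expect_lt(fd_check(function(pp) sum(w * valdec:::mlp_forward(pp, X)$out),
                     p, bk$grads, keep_attrs = attributes(p)), 1e-6)
  r <- valdec:::rnn_init(3, 5, 2, seed = 2)
  Xa <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  wr <- matrix(rnorm(4), 2, 2)
  fr <- valdec:::rnn_forward(r, Xa)
  gr <- valdec:::rnn_backward(r, fr, wr)
  expect_lt(fd_check(function(pp) sum(wr * valdec:::rnn_forward(pp, Xa)$out),
                     r, gr, keep_attrs = attributes(r)), 1e-6)
})
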