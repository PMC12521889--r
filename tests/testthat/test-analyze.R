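test_that("out-of-sample R2 helpers behave at the extremes", {
  # representations equal to the target decode perfectly
  y <- rnorm(50)
  chi <- cbind(y, matrix(rnorm(50 * 3), 50))
  pred <- valdec:::ols_fit_predict(chi[1:30, ], y[1:30], chi[31:50, ])
  expect_equal(valdec:::oos_r2(y[31:50], pred), 1)
  # label-shuffled control gives no held-out skill
  r2s <- with_seed(8, vapply(1:20, function(k) {
    ys <- sample(y)
    p <- valdec:::ols_fit_predict(chi[1:30, ], ys[1:30], chi[31:50, ])
    valdec:::oos_r2(ys[31:50], p)
  }, 0))
  expect_lt(mean(r2s), 0.1)
})

test_that("representation decoding recovers value information from a
           trained agent", {
  # full-scale trained agents: OLS on 100-dim representations needs the
  # 480-trial training split to be well determined.  The underlying claim
  # is group-level (positive mean R^2 over sessions), so it is asserted
  # across the cached choice-decoding sessions.
  rds <- lapply(t4_run()$objects, function(ob)
    decode_values_from_representations(ob$agent, ob$scaled$scaled,
                                       ob$session$behavior, ob$split))
  expect_identical(rds[[1]]$target,
                   c("value_first", "value_second", "value_difference"))
  r2mat <- do.call(cbind, lapply(rds, function(r) r$r2))
  expect_true(all(rowMeans(r2mat) > 0))
  # the difference signal is what the choice read-out is built from
  expect_true(all(r2mat[3, ] > 0))
})

test_that("timecourse decoding: chance on zero-gain data, fold guard", {
  s0 <- generate_session(simulator_config(n_trials = 150, n_cells = 8,
                                          tuning_gain_mean = 0,
                                          tuning_gain_sd = 0, seed = 9))
  tc <- timecourse_value_decoding(s0$spikes, s0$behavior, repeats = 2,
                                  seed = 3)
  expect_lt(max(tc$r2), 0.06)
  expect_error(timecourse_value_decoding(s0$spikes[1:3, , , drop = FALSE],
                                         s0$behavior[1:3, ]), "folds")
})

test_that("expected-gradients attribution matches exhaustive Shapley on
           linear models", {
  # exact Shapley by enumeration over all coalitions, background-averaged
  exact_shapley <- function(w, b0, x, bg) {
    p <- length(w)
    f <- function(mask) {
      vals <- vapply(seq_len(nrow(bg)), function(r) {
        z <- ifelse(mask, x, bg[r, ])
        sum(w * z) + b0
      }, 0)
      mean(vals)
    }
    phi <- numeric(p)
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
    for (i in seq_len(p)) {
      for (r in seq_len(nrow(subsets))) {
        S <- as.logical(subsets[r, ])
        if (S[i]) next
        k <- sum(S)
        wgt <- factorial(k) * factorial(p - k - 1) / factorial(p)
        Si <- S; Si[i] <- TRUE
        phi[i] <- phi[i] + wgt * (f(Si) - f(S))
      }
    }
    phi
  }
  for (p_dim in c(3, 7)) {
    w <- with_seed(p_dim, rnorm(p_dim))
    x <- with_seed(p_dim + 1, rnorm(p_dim))
    bg <- with_seed(p_dim + 2, matrix(rnorm(6 * p_dim), 6))
    phi <- exact_shapley(w, 0.3, x, bg)
    grad_fn <- function(X) array(rep(w, length(X) / p_dim), dim(X))
    est <- shapley_expected_gradients(grad_fn,
                                      array(x, c(p_dim, 1, 1)),
                                      array(t(bg), c(p_dim, 1, 6)),
                                      n_samples = 4000, seed = 5)
    expect_lt(max(abs(as.vector(est) - phi)) / max(abs(phi)), 0.05)
  }
})

test_that("temporal attribution normalizes and finds the informative bins", {
  agent <- trained_small_agent()
  sc <- small_scaled()
  te <- sc$split$test
  bg <- sc$Xa[, , sc$split$train[1:40], drop = FALSE]
  at <- shapley_time_attribution(agent, sc$Xa[, , te[1:40], drop = FALSE],
                                 bg, n_samples = 20, seed = 6)
  expect_equal(sum(at$per_bin), 1, tolerance = 1e-9)
  expect_true(all(at$per_bin >= 0))
  # the late (post-latency) bins carry the most credit in this world
  expect_gt(sum(at$per_bin[9:12]), sum(at$per_bin[1:4]))
  expect_error(shapley_expected_gradients(function(X) X, array(0, c(2, 1)),
                                          array(0, c(2, 1)),
                                          n_samples = 0), "n_samples")
})

test_that("accuracy by value difference: conditions, NA handling, oracle
           difficulty ordering", {
  s <- small_session()
  o <- bayes_oracle_accuracy(s)
  avd <- accuracy_by_value_difference(s$behavior, o$predicted)
  expect_identical(avd$delta, 0:4)
  got <- avd[!is.na(avd$accuracy), ]
  expect_gt(got$accuracy[nrow(got)], got$accuracy[1])  # easier when |dv| big
  # random predictions sit at chance in every populated condition
  rnd <- with_seed(3, sample(1:2, 200, replace = TRUE))
  avr <- accuracy_by_value_difference(s$behavior, rnd)
  expect_true(all(abs(avr$accuracy - 0.5) < 0.2, na.rm = TRUE))
  # an empty condition is reported as missing, not zero
  b2 <- s$behavior[abs(s$behavior$value_first - s$behavior$value_second) != 4, ]
  av2 <- accuracy_by_value_difference(b2, rep(1L, nrow(b2)))
  expect_true(is.na(av2$accuracy[av2$delta == 4]))
  expect_identical(av2$n[av2$delta == 4], 0L)
})
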