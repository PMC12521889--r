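test_that("ensemble uncertainty: printed cases and validation", {
  mk <- function(p) {
    probs <- array(NA_real_, c(5, 3, 2))
    for (m in 1:5) probs[m, , ] <- matrix(p[[m]], 3, 2, byrow = TRUE)
    probs
  }
  # 5 identical confident members: no uncertainty at all
  r1 <- ensemble_uncertainty(mk(rep(list(c(1, 0)), 5)))
  expect_equal(unname(r1$mean), c(0, 0, 0))
  # 5 identical maximally unsure members: all aleatoric
  r2 <- ensemble_uncertainty(mk(rep(list(c(0.5, 0.5)), 5)))
  expect_equal(unname(r2$mean[c("TU", "AU")]), c(log(2), log(2)))
  expect_equal(unname(r2$mean["EU"]), 0)
  # 3-vs-2 confident disagreement: purely epistemic, H(0.6, 0.4)
  r3 <- ensemble_uncertainty(mk(c(rep(list(c(1, 0)), 3),
                                  rep(list(c(0, 1)), 2))))
  h64 <- -(0.6 * log(0.6) + 0.4 * log(0.4))
  expect_equal(unname(r3$mean["AU"]), 0)
  expect_equal(unname(r3$mean["TU"]), h64)
  expect_equal(unname(r3$mean["EU"]), h64)
  expect_equal(round(h64, 4), 0.673)
  # ensemble prediction is the argmax of member-averaged probabilities
  expect_identical(r3$predicted, rep(1L, 3))
  bad <- mk(rep(list(c(0.7, 0.7)), 5))
  expect_error(ensemble_uncertainty(bad), "not normalized")
  bad2 <- mk(rep(list(c(1.4, -0.4)), 5))
  expect_error(ensemble_uncertainty(bad2), "outside")
})

test_that("kernel classifier and recurrent baseline separate a toy problem", {
  with_seed(77, {
    n <- 80
    y <- rep(1:2, n / 2)
    X <- array(rnorm(6 * 4 * n, sd = 0.3), c(6, 4, n))
    X[1, , y == 2] <- X[1, , y == 2] + 3      # two disjoint clusters
  })
  Xf <- t(matrix(X, ncol = n))
  km <- kernel_rbf_fit(Xf[1:60, ], y[1:60])
  expect_identical(max.col(kernel_rbf_predict(km, Xf[61:80, ])), y[61:80])
  rm_ <- rnn_classifier_fit(X[, , 1:60], y[1:60], hidden = 16, epochs = 40,
                            seed = 1)
  expect_identical(max.col(rnn_classifier_predict(rm_, X[, , 61:80])),
                   y[61:80])
  expect_error(kernel_rbf_fit(Xf[1:10, ], rep(1, 10)), "single class")
  expect_error(rnn_classifier_fit(X[, , 1:10], rep(2, 10)), "single class")
})

test_that("supervised baselines track the session's decodability", {
  sc <- small_scaled()
  bl <- memo("baselines_small", {
    train_supervised_baselines(sc$scaled, sc$session$behavior$choice,
                               folds = 5, seed = 3, rnn_epochs = 30)
  })
  expect_gt(bl$accuracy["kernel"], 0.6)
  expect_gt(bl$accuracy["rnn"], 0.6)
  # label-shuffled control collapses to chance
  ysh <- with_seed(9, sample(sc$session$behavior$choice))
  blsh <- train_supervised_baselines(sc$scaled, ysh, folds = 3, seed = 3,
                                     rnn_epochs = 10)
  expect_lt(max(blsh$accuracy), 0.62)
})

test_that("truncated-input evaluation: exactness at full cutoff, chance at
           the earliest cutoff, bounds checking", {
  sc <- small_scaled()
  y <- sc$session$behavior$choice
  tr <- sc$split$train; te <- sc$split$test
  Xf <- matrix(sc$scaled, dim(sc$scaled)[1])
  km <- kernel_rbf_fit(Xf[tr, ], y[tr])
  pred_fn <- function(X) {
    n <- dim(X)[3]
    kernel_rbf_predict(km, t(matrix(X, ncol = n)))
  }
  Xte <- sc$Xa[, , te, drop = FALSE]
  full <- mean(max.col(pred_fn(Xte)) == y[te])
  tie <- truncated_input_evaluation(pred_fn, Xte, y[te],
                                    cutoffs = c(2, 12),
                                    n_permutations = 30, seed = 5)
  expect_identical(tie$accuracy[tie$cutoff == 12], full)   # nothing permuted
  expect_lt(abs(tie$accuracy[tie$cutoff == 2] - 0.5), 0.12)
  expect_error(truncated_input_evaluation(pred_fn, Xte, y[te], cutoffs = 13),
               "cutoff")
})

test_that("decoder ensembles produce valid probabilities and reports", {
  sc <- small_scaled()
  y <- sc$session$behavior$choice
  ens <- train_ensemble(sc$scaled, y, sc$split, family = "kernel_svc",
                        seed = 4)
  expect_identical(dim(ens$probs), c(5L, length(sc$split$test), 2L))
  expect_true(all(abs(apply(ens$probs, c(1, 2), sum) - 1) < 1e-6))
  expect_gte(min(ens$report$EU), -1e-9)
  expect_gt(ens$accuracy, 0.55)
})
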