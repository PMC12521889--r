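test_that("split sizes round half up and splits are reproducible", {
  expect_length(split_trials(630, 0.2, 1)$train, 126)
  expect_length(split_trials(623, 0.8, 1)$train, 498)   # round(498.4)
  s1 <- split_trials(500, 0.5, 42)
  s2 <- split_trials(500, 0.5, 42)
  expect_identical(s1$train, s2$train)
  expect_identical(sort(c(s1$train, s1$test)), 1:500)
  expect_error(split_trials(10, 0), "fraction")
  expect_error(split_trials(3, 0.05), "empty")
})

test_that("scaler maps training features onto [-1, 1] exactly", {
  # two-point feature -> endpoints; arithmetic progression stays one
  x <- array(0, c(5, 1, 2))
  x[, 1, 1] <- c(2, 6, 2, 6, 2)
  x[, 1, 2] <- 1:5
  sc <- fit_apply_scaler(x, 1:5)
  expect_equal(sort(unique(sc$scaled[, 1, 1])), c(-1, 1))
  expect_equal(sc$scaled[, 1, 2], c(-1, -0.5, 0, 0.5, 1))
})

test_that("scaler degenerate and held-out behavior", {
  x <- array(rnorm(40 * 3 * 2), c(40, 3, 2))
  x[, 2, 1] <- 7                              # constant feature
  sc <- fit_apply_scaler(x, 1:30)
  expect_true(all(sc$scaled[, 2, 1] == 0))
  expect_true(all(sc$scaled >= -1 & sc$scaled <= 1))
  tr <- sc$scaled[1:30, , , drop = FALSE]
  # training min/max hit the interval endpoints for live features
  for (cc in c(1, 3)) for (bb in 1:2) {
    expect_equal(min(tr[, cc, bb]), -1)
    expect_equal(max(tr[, cc, bb]), 1)
  }
  # z-stage training mean is zero: reconstruct from stats
  expect_true(all(abs(apply(x[1:30, , , drop = FALSE], c(2, 3), mean) -
                        sc$stats$mean) < 1e-9))
  # no leakage: content of held-out trials never touches the stats
  x2 <- x
  x2[31:40, , ] <- rnorm(10 * 3 * 2) * 100
  sc2 <- fit_apply_scaler(x2, 1:30)
  expect_identical(sc$stats, sc2$stats)
  expect_identical(sc$scaled[1:30, , ], sc2$scaled[1:30, , ])
  expect_error(fit_apply_scaler(x, integer(0)), "empty")
})

test_that("augmentation jitters within bounds and copies labels exactly", {
  sc <- small_scaled()
  tr <- sc$scaled[sc$split$train, , , drop = FALSE]
  a0 <- augment_trials(tr, noise_bound = 0, multiplier = 2, seed = 1)
  expect_identical(dim(a0$x)[1], 2L * dim(tr)[1])
  expect_equal(a0$x[1:dim(tr)[1], , ], tr[, , ], ignore_attr = TRUE)
  a1 <- augment_trials(tr, noise_bound = 0.1, seed = 1)
  expect_true(all(a1$x >= -1 & a1$x <= 1))
  expect_true(all(abs(a1$x - tr) <= 0.1 + 1e-12))
  # upper-tail clipping: a feature at 1.0 stays within [0.9, 1.0]
  xt <- tr; xt[] <- 1
  a2 <- augment_trials(xt, noise_bound = 0.1, seed = 2)
  expect_true(all(a2$x >= 0.9 & a2$x <= 1))
  # label marginals preserved: every source trial appears exactly
  # `multiplier` times
  expect_identical(a0$source, rep(seq_len(dim(tr)[1]), 2))
  expect_error(augment_trials(tr, noise_bound = -0.1), "noise_bound")
  expect_error(augment_trials(tr, noise_bound = 0.5), "noise_bound")
})
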