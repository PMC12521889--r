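test_that("session generation: shapes, determinism, validation", {
  s <- small_session()
  expect_identical(dim(s$spikes), c(200L, 12L, 12L))
  expect_true(all(s$spikes >= 0))
  expect_true(is.integer(s$spikes))
  expect_true(all(s$behavior$choice %in% 1:2))
  expect_true(all(s$behavior$stim_first != s$behavior$stim_second))
  # bit-identical regeneration under the same config
  s2 <- generate_session(simulator_config(n_trials = 200, n_cells = 12,
                                          seed = 7))
  expect_identical(s$spikes, s2$spikes)
  expect_identical(s$behavior, s2$behavior)
  expect_error(simulator_config(n_trials = 0), "configuration error")
  expect_error(simulator_config(untuned_fraction = 1.5), "configuration error")
  expect_error(stimulus_set(value_levels = c(rep(1L, 11), 2L)),
               "value level")
})

test_that("stimulus set default covers every value level twice", {
  st <- stimulus_set()
  expect_length(st$items, 12)
  expect_true(all(tabulate(st$value_level, 5) >= 2))
})

test_that("condition enumeration is all ordered distinct pairs", {
  expect_identical(nrow(enumerate_conditions(1:4)), 12L)
  expect_identical(nrow(enumerate_conditions(1)), 0L)
  g <- enumerate_conditions(1:5)
  expect_identical(nrow(g), 20L)
  expect_true(all(g$first != g$second))
  expect_identical(nrow(unique(g)), 20L)
})

test_that("choice law: near-deterministic at |dv| >= 2, monotone in |dv|", {
  # Monte-Carlo oracle for the subjective-jitter choice rule itself
  st <- stimulus_set()
  n <- 1e5
  draws <- with_seed(101, {
    i1 <- sample(12, n, replace = TRUE)
    i2 <- vapply(i1, function(f) sample((1:12)[-f], 1L), integer(1))
    v1 <- st$value_level[i1]; v2 <- st$value_level[i2]
    ch <- ifelse(v1 + rnorm(n, 0, 0.7) >= v2 + rnorm(n, 0, 0.7), 1L, 2L)
    data.frame(d = abs(v1 - v2),
               hi = ifelse(v1 >= v2, 1L, 2L), ch = ch)
  })
  p_hi <- vapply(1:4, function(k)
    mean((draws$ch == draws$hi)[draws$d == k]), 0)
  expect_gte(min(p_hi[2:4]), 0.95)          # |dv| >= 2
  expect_true(all(diff(p_hi) >= -0.01))     # monotone non-decreasing in |dv|
})

test_that("likelihood-ratio oracle: chance on zero-gain sessions,
           informative on default sessions, subjective signal at dv = 0", {
  s0 <- generate_session(simulator_config(n_trials = 300, n_cells = 12,
                                          tuning_gain_mean = 0,
                                          tuning_gain_sd = 0, seed = 5))
  o0 <- bayes_oracle_accuracy(s0)
  expect_lt(abs(o0$accuracy - 0.5), 0.08)
  s <- small_session()
  o <- bayes_oracle_accuracy(s)
  expect_gt(o$accuracy, 0.7)
  # zero-difference trials stay predictable above chance (shared latent)
  d0 <- with(s$behavior, value_first == value_second)
  hits <- sum((o$predicted == s$behavior$choice)[d0])
  expect_lt(binom.test(hits, sum(d0), 0.5, "greater")$p.value, 0.05)
  expect_error(bayes_oracle_accuracy(s, simulator_config(n_cells = 5)),
               "inconsistent")
})

test_that("latency structure: first value decodable early, second only late", {
  # the early first-value trace is weak by design (prefix-only choice
  # decoding must stay near chance), so detecting it needs a large session
  s <- generate_session(simulator_config(n_trials = 1500, seed = 13))
  tc <- timecourse_value_decoding(s$spikes, s$behavior, repeats = 2,
                                  seed = 17)
  early <- tc$bin <= 8     # bins fully before +0.2 s
  v1e <- tc$r2[tc$target == "value_first" & early]
  v2e <- tc$r2[tc$target == "value_second" & early]
  v2l <- tc$r2[tc$target == "value_second" & tc$bin %in% 10:11]
  expect_gt(max(v1e), 0.03)        # above chance around the kappa1 peak
  expect_lt(max(v2e), 0.02)        # second value silent before latency
  expect_gt(min(v2l), 0.3)         # and strong after
})
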