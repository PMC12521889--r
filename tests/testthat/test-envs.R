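mk_feats <- function(n = 40, C = 4, Tb = 12, seed = 1)
  with_seed(seed, array(runif(C * Tb * n, -1, 1), c(C, Tb, n)))

test_that("choice environment: reward rule and chance level", {
  ch <- rep(1:2, 20)
  e <- env_choice(mk_feats(), ch, episode_length = 40, seed = 3)
  e$reset()
  i <- e$order[1]
  st <- e$step(ch[i])
  expect_identical(st$r, 1)
  st2 <- e$step(3 - ch[e$order[2]])
  expect_identical(st2$r, 0)
  expect_error(e$step(5), "action")
  rb <- random_agent_baseline(env_choice(mk_feats(), ch, 40, seed = 4),
                              n_episodes = 100, seed = 9)
  expect_lt(abs(rb - 0.5), 0.03)
})

test_that("sequence environment: scoring, termination, enumeration oracle", {
  ch <- rep(1:2, 30)
  e <- env_sequence(mk_feats(60), ch, mode = "order", episode_length = 60,
                    seed = 5)
  e$reset()
  tgt <- e$target_sequence(e$order[1])
  r <- vapply(tgt, function(a) e$step(a)$r, 0)
  expect_identical(sum(r), 4)                      # full correct sequence
  # a mistake ends the trial with no further reward
  tgt2 <- e$target_sequence(e$order[e$ptr])
  wrong <- setdiff(1:4, tgt2[1])[1]
  st <- e$step(wrong)
  expect_identical(st$r, 0)
  expect_true(st$trial_done)
  # exhaustive enumeration oracle: expected reward of a uniform-random
  # policy against one fixed length-4 sequence, stop at first error
  strings <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  score1 <- function(s, tgt) { k <- 0
    for (j in 1:4) { if (s[j] != tgt[j]) break; k <- k + 1 }
    k }
  exp_reward <- mean(apply(strings, 1, score1, tgt = c(1, 2, 3, 4)))
  expect_equal(exp_reward, 85 / 256)
  # Monte-Carlo through the environment matches the oracle
  rb <- random_agent_baseline(
    env_sequence(mk_feats(60), ch, mode = "order", episode_length = 60,
                 seed = 6), n_episodes = 40, seed = 10)
  expect_lt(abs(rb - 85 / 256 / 4), 0.012)
  # normalization denominator: sequence length x number of trials
  e100 <- env_sequence(mk_feats(120), rep(1:2, 60), mode = "order",
                       episode_length = 100, seed = 7)
  expect_identical(e100$max_reward_per_episode(), 400)
  expect_error(env_sequence(mk_feats(), ch[1:40], mode = "value"),
               "configuration error")
})

test_that("sequence map assigns distinct fixed sequences per key", {
  m1 <- sequence_map("value", seed = 8)
  expect_identical(dim(m1), c(5L, 4L))
  expect_identical(nrow(unique(m1)), 5L)
  expect_identical(m1, sequence_map("value", seed = 8))
})

test_that("per-episode augmentation redraws synthetic-trial noise only", {
  base <- mk_feats(10, seed = 2)
  pool <- array(c(base, base), c(4, 12, 20))   # 10 real + 10 synthetic
  e <- env_choice(pool, rep(1:2, 10), episode_length = 20, seed = 6)
  set_per_episode_augmentation(e, 11:20, base, noise_bound = 0.1)
  e$reset()
  f1 <- e$features
  e$reset()
  f2 <- e$features
  expect_identical(f1[, , 1:10], f2[, , 1:10])       # real trials untouched
  expect_false(identical(f1[, , 11:20], f2[, , 11:20]))
  expect_true(all(abs(f1[, , 11:20] - base) <= 0.1 + 1e-12))
  expect_true(all(f1 >= -1 & f1 <= 1))
})

test_that("masked environment: prefix masks, reproducibility, env1 parity", {
  ch <- rep(1:2, 20)
  f <- mk_feats()
  e <- env_masked(f, ch, rep(1, 40), rep(2, 40), episode_length = 40,
                  seed = 12)
  e$reset()
  ob <- e$observe()
  expect_identical(ob$mask, as.integer(seq_len(12) <= ob$cutoff))
  cuts1 <- e$cutoffs
  e2 <- env_masked(f, ch, rep(1, 40), rep(2, 40), episode_length = 40,
                   seed = 12)
  e2$reset()
  expect_identical(cuts1, e2$cutoffs)              # seeded cutoff draws
  # fixed full cutoff reproduces the choice environment's transitions
  e3 <- env_masked(f, ch, rep(1, 40), rep(2, 40), episode_length = 40,
                   cutoff = "fixed:12", seed = 33)
  e4 <- env_choice(f, ch, episode_length = 40, seed = 33)
  e3$reset(); e4$reset()
  expect_identical(e3$order, e4$order)
  expect_true(all(e3$cutoffs == 12))
  r3 <- vapply(1:40, function(i) e3$step(1)$r, 0)
  r4 <- vapply(1:40, function(i) e4$step(1)$r, 0)
  expect_identical(r3, r4)
  # masks are contiguous prefixes only; anything else is a config error
  expect_error(env_masked(f, ch, rep(1, 40), rep(2, 40),
                          cutoff = "random_bins", seed = 1),
               "configuration error")
  expect_error(env_masked(f, ch, rep(1, 40), rep(2, 40),
                          cutoff = "fixed:40", seed = 1),
               "configuration error")
})
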