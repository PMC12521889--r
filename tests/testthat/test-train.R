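test_that("Q-learning target", {
  expect_identical(q_target(1, c(0.2, 0.5), g = 0), 1)
  expect_equal(q_target(1, c(0.2, 0.5), g = 0.99, terminal = FALSE), 1.495)
  expect_identical(q_target(0.7, NULL, g = 0.99), 0.7)   # terminal
})

test_that("soft target update", {
  tgt <- list(w = matrix(0, 2, 2), b = c(0, 0))
  onl <- list(w = matrix(1, 2, 2), b = c(1, 1))
  expect_equal(soft_update(tgt, onl, 1), onl)
  expect_equal(soft_update(tgt, onl, 0), tgt)
  up <- soft_update(tgt, onl, 0.005)
  expect_equal(up$w[1, 1], 0.005)
  expect_error(soft_update(list(w = matrix(0, 2, 2)),
                           list(w = matrix(0, 3, 2)), 0.5), "shape")
  expect_error(soft_update(tgt, onl, 2), "rho")
})

test_that("replay buffer: FIFO eviction and uniform sampling", {
  b <- replay_buffer(capacity = 50, n_cols = 2)
  b$add(cbind(1:60, 0))
  expect_identical(b$size(), 50L)
  expect_identical(b$data[1, 1], 11)               # oldest evicted
  # chi-square uniformity of sampled row indices
  b2 <- replay_buffer(100, 1)
  b2$add(matrix(1:40, ncol = 1))
  counts <- integer(40)
  with_seed(5, for (k in 1:2000) {
    s <- b2$sample(10)
    counts[s[, 1]] <- counts[s[, 1]] + 1L
  })
  chisq <- sum((counts - mean(counts))^2 / mean(counts))
  expect_gt(pchisq(chisq, df = 39, lower.tail = FALSE), 1e-4)
})

small_train_setup <- function() memo("small_train_setup", {
  sc <- small_scaled()
  tr <- sc$split$train
  list(feats = sc$Xa[, , tr, drop = FALSE],
       choice = sc$session$behavior$choice[tr],
       sf = sc$session$behavior$stim_first[tr],
       ss = sc$session$behavior$stim_second[tr],
       Xte = sc$Xa[, , sc$split$test, drop = FALSE],
       yte = sc$session$behavior$choice[sc$split$test],
       session = sc$session, split = sc$split, scaled = sc$scaled)
})

test_that("training loop: determinism, no-op at zero iterations, learning", {
  st <- small_train_setup()
  mk <- function() env_choice(st$feats, st$choice, episode_length = 50,
                              seed = 21)
  agent <- core_agent(12, 12, d_model = 32, n_heads = 2, d_ff = 48,
                      seed = 22)
  cfg <- train_config(n_iterations = 12, batch_size = 64, seed = 23)
  t1 <- train_agent(mk(), agent, cfg)
  t2 <- train_agent(mk(), agent, cfg)
  expect_identical(t1$log, t2$log)                 # fully seeded
  expect_equal(t1$agent$tf$W_e, t2$agent$tf$W_e)
  t0 <- train_agent(mk(), agent, train_config(n_iterations = 0))
  expect_identical(t0$agent$tf, agent$tf)
  expect_identical(nrow(t0$log), 0L)
  # loss is finite and the agent moves off its zero-Q initialization
  expect_true(all(is.finite(t1$log$loss)))
  expect_gt(max(abs(t1$agent$head$W1)), 0)
})

test_that("forecaster training: contract, improvement, frozen in agent", {
  st <- small_train_setup()
  expect_error(train_forecaster(st$scaled, st$split,
                                srnn_init(12, seed = 1),
                                trials = st$split$test[1:5]),
               "contract violation")
  fc0 <- srnn_init(12, hidden = 32, latent = 16, enc_hidden = 32, seed = 2)
  tin <- tag_inputs(st$session$behavior, NULL, st$session$config)
  te <- st$split$test
  Xa <- aperm(st$scaled, c(2, 3, 1))
  pre <- forecast_fill(fc0, Xa[, , te], tin[, , te], 6, "reconstruct")
  pre_err <- mean((pre[, 7:12, ] - Xa[, 7:12, te])^2)
  tr <- train_forecaster(st$scaled, st$split, fc0, NULL, epochs = 40,
                         batch_size = 64, lr = 2e-3, seed = 3)
  post <- forecast_fill(tr$forecaster, Xa[, , te], tin[, , te], 6,
                        "reconstruct")
  post_err <- mean((post[, 7:12, ] - Xa[, 7:12, te])^2)
  expect_lt(post_err, pre_err)
  # held-out reconstruction beats predicting the mean
  expect_lt(post_err, var(as.vector(Xa[, 7:12, te])))
  # the forecaster is frozen during combined-agent training
  ag <- combined_agent(12, 12, tr$forecaster, NULL, d_model = 32,
                       n_heads = 2, d_ff = 48, seed = 4)
  env <- env_masked(st$feats, st$choice, st$sf, st$ss,
                    episode_length = 50, seed = 5)
  out <- train_agent(env, ag, train_config(n_iterations = 3,
                                           batch_size = 64, seed = 6),
                     tags_in = tin[, , st$split$train, drop = FALSE])
  expect_identical(out$forecaster_checksum[1], out$forecaster_checksum[2])
})

test_that("sequence-task training learns above the random baseline", {
  st <- small_train_setup()
  env <- env_sequence(st$feats, st$choice, mode = "order",
                      episode_length = 64, seed = 31)
  agent <- sequence_agent(12, 12, d_model = 32, n_heads = 2, d_ff = 48,
                          seed = 32)
  out <- train_env2_agent(env, agent,
                          train_config(n_iterations = 60, discount = 0.99,
                                       batch_size = 128, seed = 33))
  # evaluation must share the session's fixed sequence map
  ev_env <- env_sequence(st$feats, st$choice, mode = "order",
                         episode_length = 64, seed = 34,
                         seq_map = env$map)
  ev <- evaluate_env2_agent(out$agent, ev_env, n_episodes = 3)
  chance <- 85 / 256 / 4
  expect_gt(ev$normalized_reward, chance + 0.05)
  # the representation component's decoding bounds the agent's sequencing
  expect_gte(ev$choice_accuracy + 0.05, ev$normalized_reward)
  # value-mapped mode with zero regularizer runs the same loss structure
  beh_tr <- st$session$behavior[st$split$train, ]
  chosen_value <- ifelse(st$choice == 1, beh_tr$value_first,
                         beh_tr$value_second)
  envv <- env_sequence(st$feats, st$choice, values = chosen_value,
                       mode = "value", episode_length = 64, seed = 35)
  outv <- train_env2_agent(envv, sequence_agent(12, 12, d_model = 32,
                                                n_heads = 2, d_ff = 48,
                                                seed = 36),
                           train_config(n_iterations = 5, discount = 0.99,
                                        batch_size = 64, cql_weight = 0.1,
                                        seed = 37))
  expect_true(all(is.finite(outv$log$q_loss)))
})
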