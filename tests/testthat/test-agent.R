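test_that("training schedule validates and reports its bookkeeping", {
  s <- training_schedule()
  expect_equal(s$episodes, 40000L)
  expect_equal(s$warmup_episodes, 4000L)
  expect_equal(s$noise_profiles, 15L)
  expect_equal(s$warmup_episodes * s$noise_profiles, 60000L)
  expect_error(training_schedule(episodes = 100, warmup_episodes = 100))
  # exploration anneals from sd0 to exactly zero at the final episode
  expect_equal(mossddpg:::.exploration_sd(s, 1), s$exploration_sd0)
  expect_equal(mossddpg:::.exploration_sd(s, s$episodes), 0)
  mid <- mossddpg:::.exploration_sd(s, s$episodes %/% 2)
  expect_true(mid > 0 && mid < s$exploration_sd0)
})

test_that("compiled LSTM core agrees with the plain-R reference", {
  set.seed(11)
  B <- 6; TT <- 5; d <- 4; h <- 7
  X <- array(rnorm(B * TT * d), c(B, TT, d))
  Xf <- matrix(X, B * TT, d)
  p <- mossddpg:::lstm_init(d, h)
  fwd_ref <- mossddpg:::lstm_forward(p, X)
  H_cpp <- mossddpg:::lstm_H_cpp(p$Wx, p$Wh, p$b, Xf, B, TT)
  expect_equal(H_cpp, fwd_ref$H, tolerance = 1e-14)
  dH <- matrix(rnorm(B * h), B, h)
  g_ref <- mossddpg:::lstm_backward(p, fwd_ref, dH)
  g_cpp <- mossddpg:::lstm_grad_cpp(p$Wx, p$Wh, p$b, Xf, B, TT, dH)
  expect_equal(g_cpp$Wx, g_ref$Wx, tolerance = 1e-12)
  expect_equal(g_cpp$Wh, g_ref$Wh, tolerance = 1e-12)
  expect_equal(as.numeric(g_cpp$b), g_ref$b, tolerance = 1e-12)

  # and the reference itself against finite differences
  f <- function(pp) sum(mossddpg:::lstm_forward(pp, X)$H * dH)
  for (nm in c("Wx", "Wh", "b")) {
    i <- 3L
    p2 <- p
    p2[[nm]][i] <- p2[[nm]][i] + 1e-6
    expect_equal(g_ref[[nm]][i], (f(p2) - f(p)) / 1e-6, tolerance = 1e-4)
  }
})

test_that("an untrained policy is deterministic, finite and bounded", {
  env <- quadratic_env(kappa = 0.4)
  set.seed(1)
  obs <- env_reset(env)
  sched <- training_schedule(episodes = 10, warmup_episodes = 9,
                             noise_profiles = 2, hidden = 8,
                             critic_hidden = 8, batch_size = 4)
  fit <- moss_ddpg(env, sched, seed = 2)
  a1 <- predict(fit, obs)
  a2 <- predict(fit, obs)
  expect_identical(a1, a2)
  expect_true(all(is.finite(a1)))
  expect_true(all(abs(a1) <= fit$action_limit))
  expect_identical(names(a1), as.character(4:15))
  expect_error(predict(fit, obs[1:10, ]))
  q <- critic_value(fit, obs, a1)
  expect_true(is.finite(q))
})

test_that("replay bookkeeping stores episodes x k transitions", {
  env <- quadratic_env(kappa = 0.4, target_indices = 4:5,
                       noise_indices = 16:17)
  sched <- training_schedule(episodes = 30, warmup_episodes = 10,
                             noise_profiles = 5, hidden = 8,
                             critic_hidden = 8, batch_size = 16)
  env_image_count(env, reset = TRUE)
  fit <- moss_ddpg(env, sched, seed = 3)
  expect_equal(fit$n_transitions, 30 * 5)
  expect_equal(fit$replay_occupancy, 150)
  expect_length(fit$reward_trace, 30)
  # (2N+1) observations + k evaluations per episode
  expect_equal(env_image_count(env), 30 * (2 * 2 + 1 + 5))
})

test_that("training runs are reproducible under a fixed master seed", {
  env <- quadratic_env(kappa = 0.4, target_indices = 4:5,
                       noise_indices = 16:17)
  sched <- training_schedule(episodes = 25, warmup_episodes = 5,
                             noise_profiles = 4, hidden = 8,
                             critic_hidden = 8, batch_size = 16)
  f1 <- moss_ddpg(env, sched, seed = 7)
  f2 <- moss_ddpg(env, sched, seed = 7)
  expect_identical(f1$reward_trace, f2$reward_trace)
  expect_identical(f1$actor, f2$actor)
})

test_that("checkpoints round-trip through JSON without losing the policy", {
  env <- quadratic_env(kappa = 0.4, target_indices = 4:6,
                       noise_indices = 16:18)
  sched <- training_schedule(episodes = 12, warmup_episodes = 4,
                             noise_profiles = 3, hidden = 8,
                             critic_hidden = 8, batch_size = 8)
  fit <- moss_ddpg(env, sched, seed = 4)
  set.seed(5)
  obs <- env_reset(env)
  path <- tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  expect_equal(predict(fit2, obs), predict(fit, obs), tolerance = 1e-12)
  expect_equal(critic_value(fit2, obs, predict(fit, obs)),
               critic_value(fit, obs, predict(fit, obs)), tolerance = 1e-12)
  expect_equal(fit2$schedule$noise_profiles, 3L)
  expect_error(load_checkpoint(tempfile()))
})

test_that("transfer learning refuses a mode-count mismatch", {
  env3 <- quadratic_env(kappa = 0.4, target_indices = 4:6,
                        noise_indices = 16:18)
  sched <- training_schedule(episodes = 10, warmup_episodes = 2,
                             noise_profiles = 2, hidden = 8,
                             critic_hidden = 8, batch_size = 4)
  fit <- moss_ddpg(env3, sched, seed = 6)
  env12 <- quadratic_env(kappa = 0.4)
  expect_error(transfer_learn(fit, env12), "mismatch")
})

test_that("the default transfer schedule is 2.5% of the training episodes", {
  expect_equal(formals(transfer_learn)$episodes, 1000)
  expect_equal(formals(transfer_learn)$noise_profiles, 7)
  expect_equal(1000 / formals(training_schedule)$episodes, 0.025)
})
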