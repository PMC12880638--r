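test_that("the PPO core learns a simple steer-to-target control problem", {
  set.seed(2)
  x <- NULL; tgt <- NULL; t <- 0
  env <- list(
    reset = function() {
      x <<- sample(1:9, 1); tgt <<- sample(1:9, 1); t <<- 0
      c((x - 1) / 8, (tgt - x) / 8)
    },
    step = function(a) {
      dx <- c(-1L, 0L, 1L)[a + 1]
      x <<- min(max(x + dx, 1L), 9L); t <<- t + 1
      list(obs = c((x - 1) / 8, (tgt - x) / 8),
           reward = as.numeric(x == tgt), done = t >= 50)
    })
  fit <- soctask:::ppo_train(env, 2L, 3L,
                             ppo_hp(n_steps = 500, gamma = 0.95,
                                    learning_rate = 2e-3), 20000)
  cv <- fit$curve
  expect_gt(mean(utils::tail(cv$mean_step_reward, 3)),
            2 * mean(utils::head(cv$mean_step_reward, 3)))
})

test_that("gradients match finite differences of the clipped objective", {
  set.seed(3)
  d <- 4L; A <- 3L; n <- 10L
  par <- soctask:::mlp_init(d, A, 6L)
  X <- matrix(rnorm(n * d), n, d)
  actions <- sample(0:(A - 1L), n, TRUE)
  logp_old <- log(runif(n, 0.2, 0.5))
  adv <- rnorm(n); ret <- rnorm(n)
  hp <- ppo_hp()
  loss <- function(par) {
    f <- soctask:::mlp_forward(par, X)
    lp <- soctask:::log_softmax(f$logits)
    P <- exp(lp)
    ia <- cbind(seq_len(n), actions + 1L)
    ratio <- exp(lp[ia] - logp_old)
    clipped <- pmax(pmin(ratio, 1 + hp$clip), 1 - hp$clip)
    -mean(pmin(ratio * adv, clipped * adv)) -
      hp$ent_coef * mean(-rowSums(P * lp)) +
      hp$vf_coef * mean((f$v - ret)^2)
  }
  g <- soctask:::ppo_grads(par, X, actions, logp_old, adv, ret, hp)
  for (nm in names(par)) {
    num <- par[[nm]] * 0
    for (i in seq_along(par[[nm]])) {
      p1 <- par; p1[[nm]][i] <- p1[[nm]][i] + 1e-6
      p2 <- par; p2[[nm]][i] <- p2[[nm]][i] - 1e-6
      num[i] <- (loss(p1) - loss(p2)) / 2e-6
    }
    expect_lt(max(abs(num - g[[nm]])), 1e-6)
  }
})

test_that("a zero-step budget returns the untrained policy unchanged", {
  cfg <- env_config("easy")
  ck <- train_sub_agent(cfg, train_config("sub_agent", total_steps = 0,
                                          seed = 5))
  expect_s3_class(ck, "sub_agent_ckpt")
  expect_identical(ck$total_steps, 0L)
  expect_identical(nrow(ck$curve), 0L)
  pol <- as_sub_policy(ck)
  st <- env_reset(cfg, seed = 1)
  expect_true(pol(st, cfg) %in% 0:2)
})

test_that("consumed steps equal the budget up to one rollout batch", {
  cfg <- env_config("easy")
  hp <- ppo_hp(n_steps = 470L)
  ck <- train_sub_agent(cfg, train_config("sub_agent", total_steps = 1000,
                                          seed = 5, hp = hp))
  expect_gte(ck$total_steps, 1000L)
  expect_lt(ck$total_steps, 1000L + hp$n_steps)
  expect_identical(glance(ck)$total_steps, ck$total_steps)
})

test_that("training is reproducible under a fixed seed", {
  cfg <- env_config("easy")
  tc <- train_config("sub_agent", total_steps = 2000, seed = 9,
                     hp = ppo_hp(n_steps = 470L))
  a <- train_sub_agent(cfg, tc)
  b <- train_sub_agent(cfg, tc)
  expect_identical(a$params, b$params)
  expect_identical(a$curve, b$curve)
})

test_that("meta training freezes the sub-agents and respects reward ranges", {
  cfg <- env_config("easy")
  sub <- train_sub_agent(cfg, train_config("sub_agent", total_steps = 0,
                                           seed = 6))
  before <- serialize(sub$params, NULL)
  mk <- train_meta_agent(meta_config("soc", "soc"), list(sub, sub),
                         list(cfg, cfg),
                         train_config("meta_agent", reward_mode = "soc",
                                      total_steps = 1000, seed = 7))
  expect_identical(serialize(sub$params, NULL), before)
  expect_s3_class(mk, "meta_agent_ckpt")
  # per-decision SoC rewards are bounded by the reward table
  expect_true(all(mk$curve$mean_step_reward >= -1 &
                    mk$curve$mean_step_reward <= 1))
  expect_identical(glance(mk)$agent_label, "soc")
  pol <- as_meta_policy(mk)
  expect_true(pol(1L, c(0.5, 0.2, 1)) %in% 0:1)
})

test_that("a missing sub checkpoint is a configuration error", {
  cfg <- env_config("easy")
  expect_error(train_meta_agent(meta_config(), list(NULL, NULL),
                                list(cfg, cfg)),
               "invalid|missing")
  expect_error(train_meta_agent(meta_config(), list(greedy_policy),
                                list(cfg, cfg)),
               "two sub-agent")
})

test_that("hyperparameter search recovers a known argmax", {
  # injected dummy trainer with a deterministic quality landscape
  dummy <- function(hp) list(mean_reward = -abs(hp$gamma - 0.93), hp = hp)
  set.seed(11)
  res <- hyperparameter_search(dummy,
                               search_space = list(
                                 learning_rate = c(1e-4, 1e-3),
                                 gamma = c(0.85, 0.99),
                                 gae_lambda = c(0.9, 1),
                                 ent_coef = c(0, 0.01)),
                               n_trials = 8)
  expect_identical(nrow(res$trials), 8L)
  best_row <- which.max(res$trials$mean_reward)
  expect_equal(res$best$mean_reward, max(res$trials$mean_reward))
  expect_equal(res$best_hp$gamma, res$trials$gamma[best_row])
  # a single trial is selected trivially
  res1 <- hyperparameter_search(dummy, res1_space <- list(
    learning_rate = c(1e-4, 1e-3), gamma = c(0.85, 0.99),
    gae_lambda = c(0.9, 1), ent_coef = c(0, 0.01)), n_trials = 1)
  expect_identical(nrow(res1$trials), 1L)
  expect_equal(res1$best$mean_reward, res1$trials$mean_reward[1])
})

test_that("preset budgets follow the study's step counts", {
  expect_equal(train_config("sub_agent", preset = "paper")$total_steps, 1e7)
  expect_equal(train_config("meta_agent", preset = "paper",
                            reward_mode = "active")$total_steps, 1.3e6)
  expect_equal(train_config("meta_agent", preset = "paper",
                            reward_mode = "soc")$total_steps, 1e4)
  desk <- train_config("sub_agent", preset = "desk")$total_steps
  expect_lt(desk, 1e7)
})
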