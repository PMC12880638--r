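#' Training configuration for sub- and meta-agents
#'
#' Two presets are provided. `paper` uses the full step budgets of the
#' study conditions (sub-agents 10,000,000 environment steps; meta-agent
#' 1,300,000 decisions with the active reward, 10,000 with the SoC reward,
#' whose learning curve converges early). `desk` is a reduced preset for
#' single-CPU runs (sub 200,000; meta active 100,000; meta soc 10,000) —
#' absolute success rates undershoot the full-budget ones, ordering
#' comparisons between agents remain meaningful.
#'
#' @param target `"sub_agent"` or `"meta_agent"`.
#' @param preset `"desk"` or `"paper"`.
#' @param total_steps Override the preset step budget (environment steps
#'   for sub-agents, meta decisions for meta-agents).
#' @param reward_mode For `meta_agent` targets, which preset budget
#'   applies: `"active"` or `"soc"`.
#' @param hp A [ppo_hp()]; a target-appropriate default is built when
#'   `NULL`.
#' @param seed Integer seed recorded in the checkpoint and applied before
#'   training.
#' @param n_trials Number of hyperparameter-search trials (used by
#'   [hyperparameter_search()]).
#' @param search_space Ranges for the four tuned hyperparameters
#'   (learning rate, discount, GAE lambda, entropy coefficient).
#' @return A list of class `train_config`.
#' @export
train_config <- function(target = c("sub_agent", "meta_agent"),
                         preset = c("desk", "paper"),
                         total_steps = NULL,
                         reward_mode = c("active", "soc"),
                         hp = NULL, seed = 1L, n_trials = 1L,
                         search_space = NULL) {
  target <- match.arg(target)
  preset <- match.arg(preset)
  reward_mode <- match.arg(reward_mode)
  budgets <- list(
    paper = c(sub_agent = 1e7, meta_active = 1.3e6, meta_soc = 1e4),
    desk = c(sub_agent = 2e5, meta_active = 1e5, meta_soc = 1e4)
  )
  if (is.null(total_steps)) {
    key <- if (target == "sub_agent") "sub_agent" else
      paste0("meta_", reward_mode)
    total_steps <- budgets[[preset]][[key]]
  }
  if (is.null(hp)) {
    hp <- if (target == "sub_agent") {
      ppo_hp(hidden = 64L, learning_rate = 2e-3, gamma = 0.9,
             n_steps = 1880L, n_minibatches = 4L, reward_scale = 0.01)
    } else if (reward_mode == "soc") {
      # the SoC-difference reward is immediate, so a short credit horizon
      # and an aggressive step size converge within a small budget
      ppo_hp(hidden = 16L, learning_rate = 1e-2, gamma = 0.3,
             n_steps = 188L, n_minibatches = 4L, n_epochs = 8L,
             reward_scale = 1)
    } else {
      ppo_hp(hidden = 32L, learning_rate = 1e-3, gamma = 0.95,
             n_steps = 376L, n_minibatches = 4L, reward_scale = 0.002)
    }
  }
  if (is.null(search_space)) {
    search_space <- list(learning_rate = c(1e-4, 1e-3),
                         gamma = c(0.9, 0.999),
                         gae_lambda = c(0.8, 1.0),
                         ent_coef = c(0.0, 0.05))
  }
  structure(list(target = target, preset = preset,
                 total_steps = as.numeric(total_steps),
                 reward_mode = reward_mode, hp = hp, seed = as.integer(seed),
                 n_trials = as.integer(n_trials),
                 search_space = search_space),
            class = "train_config")
}

#' Train a sub-agent on one Collect Asteroids task
#'
#' PPO on the positional window encoding of [encode_sub_obs()]; each
#' episode draws a fresh random world. A zero-step budget returns the
#' randomly initialized policy unchanged. A warning is emitted (and the
#' checkpoint still returned) when the reward trend collapses across the
#' training run.
#'
#' @param env_cfg An [env_config()].
#' @param tc A [train_config()] with target `"sub_agent"`.
#' @return A checkpoint of class `sub_agent_ckpt`: network parameters,
#'   configs, seed, consumed steps, and the learning curve (see
#'   [generics::tidy()]).
#' @export
train_sub_agent <- function(env_cfg, tc = train_config("sub_agent")) {
  stopifnot(tc$target == "sub_agent")
  set.seed(tc$seed)
  d_in <- length(encode_sub_obs(generate_world(env_cfg), env_cfg))
  state <- NULL
  env <- list(
    reset = function() {
      state <<- generate_world(env_cfg)
      encode_sub_obs(state, env_cfg)
    },
    step = function(action) {
      out <- env_step(state, action, env_cfg)
      state <<- out$state
      list(obs = encode_sub_obs(state, env_cfg), reward = out$reward,
           done = out$done)
    }
  )
  fit <- ppo_train(env, d_in, 3L, tc$hp, tc$total_steps)
  warn_on_collapse(fit$curve)
  structure(list(params = fit$par, env_config = env_cfg, hp = tc$hp,
                 seed = tc$seed, total_steps = fit$steps_done,
                 curve = fit$curve,
                 mean_reward = mean_curve_reward(fit$curve)),
            class = "sub_agent_ckpt")
}

mean_curve_reward <- function(curve) {
  if (!nrow(curve)) return(NA_real_)
  mean(curve$mean_step_reward)
}

warn_on_collapse <- function(curve) {
  if (nrow(curve) >= 10) {
    head_r <- mean(curve$mean_step_reward[seq_len(5)])
    tail_r <- mean(utils::tail(curve$mean_step_reward, 5))
    if (is.finite(head_r) && is.finite(tail_r) &&
        tail_r < 0.5 * head_r && head_r > 0) {
      warning("training reward collapsed over the run; ",
              "checkpoint saved anyway", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Turn a trained sub-agent checkpoint into a policy function
#'
#' @param ckpt A `sub_agent_ckpt`.
#' @param deterministic Pick the argmax action (default) rather than
#'   sampling from the policy distribution.
#' @return A function `(state, config) -> action` usable wherever a
#'   sub-policy is expected.
#' @export
as_sub_policy <- function(ckpt, deterministic = TRUE) {
  stopifnot(inherits(ckpt, "sub_agent_ckpt"))
  par <- ckpt$params
  function(state, config) {
    obs <- encode_sub_obs(state, config)
    if (deterministic) ppo_act_greedy(par, obs) else ppo_act(par, obs)$action
  }
}

#' Train a meta-agent over two frozen sub-policies
#'
#' PPO over the decision-level POMDP: one step of the learner is one meta
#' decision (`decision_interval` frames in both environments). Sub-policy
#' checkpoints are frozen — the meta-agent never updates them. Each meta
#' episode draws fresh world seeds from the training RNG stream.
#'
#' @param meta_cfg A [meta_config()] selecting observation and reward mode.
#' @param sub_ckpts List of two `sub_agent_ckpt`s (or plain policy
#'   functions) controlling tasks 0 and 1.
#' @param env_cfgs List of two [env_config()]s.
#' @param tc A [train_config()] with target `"meta_agent"`.
#' @param soc_cfg A [soc_config()].
#' @return A checkpoint of class `meta_agent_ckpt`.
#' @export
train_meta_agent <- function(meta_cfg, sub_ckpts, env_cfgs,
                             tc = train_config("meta_agent"),
                             soc_cfg = soc_config()) {
  stopifnot(tc$target == "meta_agent")
  if (length(sub_ckpts) != 2L) {
    stop("two sub-agent checkpoints are required", call. = FALSE)
  }
  sub_policies <- lapply(sub_ckpts, function(s) {
    if (inherits(s, "sub_agent_ckpt")) as_sub_policy(s) else
      if (is.function(s)) s else
        stop("sub checkpoint missing or invalid", call. = FALSE)
  })
  set.seed(tc$seed)
  need_soc <- meta_cfg$observation_mode == "soc" || meta_cfg$reward_mode == "soc"
  d_in <- if (meta_cfg$observation_mode == "soc") 3L else {
    2L * length(encode_sub_obs(generate_world(env_cfgs[[1]]),
                               env_cfgs[[1]])) + 1L
  }
  mt <- NULL
  env <- list(
    reset = function() {
      seeds <- sample.int(1e6, 2L)
      mt <<- mt_reset(env_cfgs, sub_policies, meta_cfg, soc_cfg, seeds,
                      compute_soc = need_soc)
      mt_observation(mt)
    },
    step = function(action) {
      res <- mt_decision(mt, action)
      mt <<- res$mt
      r <- if (meta_cfg$reward_mode == "soc") res$reward_soc else
        res$reward_active
      list(obs = mt_observation(mt), reward = r, done = mt$done)
    }
  )
  fit <- ppo_train(env, d_in, 2L, tc$hp, tc$total_steps)
  warn_on_collapse(fit$curve)
  structure(list(params = fit$par, meta_config = meta_cfg,
                 env_configs = env_cfgs, soc_config = soc_cfg,
                 hp = tc$hp, seed = tc$seed, total_steps = fit$steps_done,
                 curve = fit$curve,
                 mean_reward = mean_curve_reward(fit$curve)),
            class = "meta_agent_ckpt")
}

#' Turn a trained meta-agent checkpoint into a meta policy
#'
#' @param ckpt A `meta_agent_ckpt`.
#' @param deterministic Pick the argmax task rather than sampling.
#' @return A function `(decision_index, observation) -> task`.
#' @export
as_meta_policy <- function(ckpt, deterministic = TRUE) {
  stopifnot(inherits(ckpt, "meta_agent_ckpt"))
  par <- ckpt$params
  function(decision_index, observation) {
    if (deterministic) ppo_act_greedy(par, observation) else
      ppo_act(par, observation)$action
  }
}

#' Random search over PPO hyperparameters
#'
#' Samples `n_trials` configurations from the search space (log-uniform for
#' the learning rate, uniform otherwise), trains each with the supplied
#' training function, and returns the trial with the highest mean training
#' reward.
#'
#' @param train_fn Function taking a [ppo_hp()] and returning an object
#'   with a `mean_reward` element (e.g. a wrapper around
#'   [train_sub_agent()]).
#' @param search_space Named list of `c(lo, hi)` ranges for
#'   `learning_rate`, `gamma`, `gae_lambda`, `ent_coef`.
#' @param n_trials Number of trials (>= 1).
#' @param base_hp Template [ppo_hp()] supplying the untuned fields.
#' @return List with `best` (the winning trial's result), `best_hp`, and
#'   `trials` (a tibble logging every trial's draw and mean reward).
#' @export
hyperparameter_search <- function(train_fn, search_space, n_trials,
                                  base_hp = ppo_hp()) {
  stopifnot(n_trials >= 1)
  trials <- vector("list", n_trials)
  results <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    draw <- list(
      learning_rate = exp(stats::runif(1, log(search_space$learning_rate[1]),
                                       log(search_space$learning_rate[2]))),
      gamma = stats::runif(1, search_space$gamma[1], search_space$gamma[2]),
      gae_lambda = stats::runif(1, search_space$gae_lambda[1],
                                search_space$gae_lambda[2]),
      ent_coef = stats::runif(1, search_space$ent_coef[1],
                              search_space$ent_coef[2])
    )
    hp <- base_hp
    hp[names(draw)] <- draw
    res <- train_fn(hp)
    results[[i]] <- res
    trials[[i]] <- tibble::tibble(trial = i,
                                  learning_rate = draw$learning_rate,
                                  gamma = draw$gamma,
                                  gae_lambda = draw$gae_lambda,
                                  ent_coef = draw$ent_coef,
                                  mean_reward = res$mean_reward)
  }
  trials <- dplyr::bind_rows(trials)
  best_i <- which.max(trials$mean_reward)
  list(best = results[[best_i]],
       best_hp = {
         hp <- base_hp
         hp$learning_rate <- trials$learning_rate[best_i]
         hp$gamma <- trials$gamma[best_i]
         hp$gae_lambda <- trials$gae_lambda[best_i]
         hp$ent_coef <- trials$ent_coef[best_i]
         hp
       },
       trials = trials)
}
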