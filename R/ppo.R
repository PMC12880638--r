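# Proximal Policy Optimization for small discrete-action problems.
#
# A compact actor-critic: one shared tanh hidden layer, a softmax policy
# head and a linear value head, trained with the clipped surrogate
# objective, generalized advantage estimation and Adam. Sized for the
# low-dimensional positional observations of this package; all arithmetic
# is plain base-R linear algebra and all randomness flows through R's
# global RNG so runs are reproducible under set.seed().

#' PPO hyperparameters
#'
#' @param hidden Hidden layer width.
#' @param learning_rate Adam step size.
#' @param gamma Discount factor of the learner (distinct from the rollout
#'   discount of the SoC model).
#' @param gae_lambda Generalized advantage estimation parameter.
#' @param clip Clipping radius of the surrogate ratio.
#' @param ent_coef Entropy bonus coefficient.
#' @param vf_coef Value-loss coefficient.
#' @param n_steps Environment steps per update batch.
#' @param n_minibatches Minibatches per epoch.
#' @param n_epochs Optimization epochs per batch.
#' @param reward_scale Factor applied to environment rewards before
#'   learning (numerical conditioning of the value targets only; reported
#'   rewards are unscaled).
#' @return A list of class `ppo_hp`.
#' @export
ppo_hp <- function(hidden = 32L, learning_rate = 3e-4, gamma = 0.99,
                   gae_lambda = 0.95, clip = 0.2, ent_coef = 0.01,
                   vf_coef = 0.5, n_steps = 1024L, n_minibatches = 4L,
                   n_epochs = 4L, reward_scale = 1) {
  stopifnot(hidden >= 1, learning_rate > 0, gamma > 0, gamma <= 1,
            gae_lambda >= 0, gae_lambda <= 1, clip > 0, n_steps >= 8)
  structure(list(hidden = as.integer(hidden), learning_rate = learning_rate,
                 gamma = gamma, gae_lambda = gae_lambda, clip = clip,
                 ent_coef = ent_coef, vf_coef = vf_coef,
                 n_steps = as.integer(n_steps),
                 n_minibatches = as.integer(n_minibatches),
                 n_epochs = as.integer(n_epochs),
                 reward_scale = reward_scale),
            class = "ppo_hp")
}

mlp_init <- function(d_in, n_actions, hidden) {
  list(
    W1 = matrix(stats::rnorm(d_in * hidden, sd = sqrt(1 / d_in)),
                d_in, hidden),
    b1 = numeric(hidden),
    # near-zero policy head: initial policy close to uniform
    W2p = matrix(stats::rnorm(hidden * n_actions, sd = 0.01),
                 hidden, n_actions),
    b2p = numeric(n_actions),
    W2v = matrix(stats::rnorm(hidden, sd = sqrt(1 / hidden)), hidden, 1),
    b2v = 0
  )
}

mlp_forward <- function(par, X) {
  H <- tanh(sweep(X %*% par$W1, 2, par$b1, `+`))
  logits <- sweep(H %*% par$W2p, 2, par$b2p, `+`)
  v <- as.numeric(H %*% par$W2v + par$b2v)
  list(H = H, logits = logits, v = v)
}

log_softmax <- function(logits) {
  m <- apply(logits, 1, max)
  z <- logits - m
  z - log(rowSums(exp(z)))
}

policy_probs <- function(par, X) {
  exp(log_softmax(mlp_forward(par, X)$logits))
}

# Sample one action; obs is a bare numeric vector.
ppo_act <- function(par, obs) {
  fw <- mlp_forward(par, matrix(obs, nrow = 1))
  lp <- log_softmax(fw$logits)
  p <- exp(lp[1, ])
  a <- sample.int(length(p), 1L, prob = p)
  list(action = a - 1L, logp = lp[1, a], value = fw$v[1])
}

ppo_act_greedy <- function(par, obs) {
  fw <- mlp_forward(par, matrix(obs, nrow = 1))
  which.max(fw$logits[1, ]) - 1L
}

compute_gae <- function(rewards, values, dones, last_value, gamma, lambda) {
  n <- length(rewards)
  adv <- numeric(n)
  gae <- 0
  for (t in n:1) {
    next_v <- if (t == n) last_value else values[t + 1L]
    next_nonterminal <- 1 - dones[t]
    delta <- rewards[t] + gamma * next_v * next_nonterminal - values[t]
    gae <- delta + gamma * lambda * next_nonterminal * gae
    adv[t] <- gae
  }
  list(adv = adv, returns = adv + values)
}

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(par)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grads[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, opt = opt)
}

# Gradient of the PPO loss on one minibatch.
ppo_grads <- function(par, X, actions, logp_old, adv, returns, hp) {
  n <- nrow(X)
  fw <- mlp_forward(par, X)
  lp <- log_softmax(fw$logits)
  P <- exp(lp)
  ia <- cbind(seq_len(n), actions + 1L)
  logp_new <- lp[ia]
  ratio <- exp(logp_new - logp_old)
  # clipped surrogate: gradient flows only where the unclipped branch wins
  active <- (adv >= 0 & ratio < 1 + hp$clip) |
    (adv < 0 & ratio > 1 - hp$clip)
  dlogp <- -adv * ratio * active / n
  dlogits <- -P * dlogp           # -dlogp * P (softmax jacobian, full part)
  dlogits[ia] <- dlogits[ia] + dlogp
  # entropy bonus: d(-ent_coef * H)/dlogits = ent_coef * P * (logP + H)
  ent <- -rowSums(P * lp)
  dlogits <- dlogits + hp$ent_coef * P * (lp + ent) / n
  dv <- matrix(hp$vf_coef * 2 * (fw$v - returns) / n, ncol = 1)
  H <- fw$H
  dH <- dlogits %*% t(par$W2p) + dv %*% t(par$W2v)
  dZ1 <- dH * (1 - H^2)
  list(W1 = t(X) %*% dZ1, b1 = colSums(dZ1),
       W2p = t(H) %*% dlogits, b2p = colSums(dlogits),
       W2v = t(H) %*% dv, b2v = sum(dv))
}

ppo_update <- function(par, opt, batch, hp) {
  n <- length(batch$actions)
  adv <- batch$adv
  adv <- (adv - mean(adv)) / (stats::sd(adv) + 1e-8)
  for (ep in seq_len(hp$n_epochs)) {
    idx <- sample.int(n)
    splits <- split(idx, rep(seq_len(hp$n_minibatches),
                             length.out = n))
    for (mb in splits) {
      g <- ppo_grads(par, batch$X[mb, , drop = FALSE], batch$actions[mb],
                     batch$logp[mb], adv[mb], batch$returns[mb], hp)
      st <- adam_step(par, g, opt, hp$learning_rate)
      par <- st$par
      opt <- st$opt
    }
  }
  list(par = par, opt = opt)
}

# Train a PPO agent against an environment interface:
#   env$reset() -> observation vector
#   env$step(action) -> list(obs, reward, done)
# Runs ceiling(total_steps / n_steps) update batches, so the consumed step
# count equals the budget up to one rollout batch. Returns the parameters
# and a per-update learning curve.
ppo_train <- function(env, d_in, n_actions, hp, total_steps) {
  par <- mlp_init(d_in, n_actions, hp$hidden)
  opt <- adam_init(par)
  n_updates <- ceiling(total_steps / hp$n_steps)
  curve <- vector("list", n_updates)
  obs <- env$reset()
  ep_ret <- 0
  ep_returns <- numeric(0)
  steps_done <- 0L
  for (u in seq_len(n_updates)) {
    ns <- hp$n_steps
    X <- matrix(0, ns, d_in)
    actions <- integer(ns)
    logp <- numeric(ns)
    values <- numeric(ns)
    rewards <- numeric(ns)
    dones <- numeric(ns)
    for (t in seq_len(ns)) {
      act <- ppo_act(par, obs)
      out <- env$step(act$action)
      X[t, ] <- obs
      actions[t] <- act$action
      logp[t] <- act$logp
      values[t] <- act$value
      rewards[t] <- out$reward * hp$reward_scale
      dones[t] <- as.numeric(out$done)
      ep_ret <- ep_ret + out$reward
      if (out$done) {
        ep_returns <- c(ep_returns, ep_ret)
        ep_ret <- 0
        obs <- env$reset()
      } else {
        obs <- out$obs
      }
    }
    steps_done <- steps_done + ns
    last_value <- if (dones[ns] == 1) 0 else {
      mlp_forward(par, matrix(obs, nrow = 1))$v[1]
    }
    g <- compute_gae(rewards, values, dones, last_value, hp$gamma,
                     hp$gae_lambda)
    upd <- ppo_update(par, opt, list(X = X, actions = actions, logp = logp,
                                     adv = g$adv, returns = g$returns), hp)
    par <- upd$par
    opt <- upd$opt
    curve[[u]] <- tibble::tibble(
      update = u, steps = steps_done,
      mean_step_reward = mean(rewards) / hp$reward_scale,
      mean_episode_return = if (length(ep_returns)) mean(ep_returns)
                            else NA_real_)
    ep_returns <- numeric(0)
  }
  list(par = par,
       curve = if (n_updates) dplyr::bind_rows(curve) else
         tibble::tibble(update = integer(), steps = integer(),
                        mean_step_reward = numeric(),
                        mean_episode_return = numeric()),
       steps_done = steps_done)
}
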