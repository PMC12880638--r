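#' Encode a subtask state as a fixed-length positional vector
#'
#' The visible pending asteroids are listed in arrival order (smallest
#' rows-to-go first), one slot each holding the scaled rows-to-go and the
#' scaled horizontal offset to the ship; unused slots carry a 0 sentinel.
#' The ship column and the episode-time fraction complete the vector.
#' Constant dimensionality (`2 * slots + 2`) regardless of how many
#' asteroids remain.
#'
#' @param state A `world_state`.
#' @param config An [env_config()].
#' @param slots Number of asteroid slots (default 5).
#' @return Numeric vector of length `2 * slots + 2`.
#' @export
encode_sub_obs <- function(state, config, slots = 5L) {
  out <- numeric(2L * slots)
  vis <- visible_relative(state, config)
  if (length(vis$dy)) {
    ord <- order(vis$dy)
    n <- min(slots, length(ord))
    out[seq_len(n) * 2L - 1L] <- vis$dy[ord[seq_len(n)]] / config$window
    out[seq_len(n) * 2L] <- vis$dx[ord[seq_len(n)]] /
      (config$corridor_width - 1L)
  }
  c(out,
    (state$ship_x - 1L) / (config$corridor_width - 1L),
    state$step / config$episode_length)
}

#' Assemble the meta-agent's observation
#'
#' Concatenates ground truth about the active task with a belief about the
#' inactive one. In `world_state` mode both parts are positional encodings
#' (the inactive side a forward-model-propagated belief); in `soc` mode the
#' parts are the two tasks' SoC values (the inactive one a decayed
#' estimate). An explicit active-task indicator is appended.
#'
#' @param active_part Encoded true state (or measured SoC) of the active
#'   task.
#' @param inactive_part Encoded believed state (or SoC estimate) of the
#'   inactive task.
#' @param active_task Which task (0/1) the active part refers to.
#' @param meta_cfg A [meta_config()].
#' @return Numeric observation vector; task 0's representation always comes
#'   first so the layout is stable across activations.
#' @export
build_meta_observation <- function(active_part, inactive_part, active_task,
                                   meta_cfg) {
  if (active_task == 0L) {
    c(active_part, inactive_part, 0)
  } else {
    c(inactive_part, active_part, 1)
  }
}

#' Aggregate the active sub-agent's reward over a decision slice
#'
#' @param sub_rewards Rewards collected by the active environment over the
#'   `decision_interval` frames of one meta decision.
#' @return Their sum.
#' @export
active_reward <- function(sub_rewards) sum(sub_rewards)

#' Switch-every-frame baseline policy
#'
#' Toggles the chosen task at every decision point, starting with task 0;
#' relative to the pre-episode reference task this realizes a switch at
#' every one of the `episode_length / decision_interval` decisions (94
#' under the default geometry).
#'
#' @param decision_index 1-based decision counter.
#' @param observation Ignored.
#' @return Task 0 or 1.
#' @export
switch_every_frame_policy <- function(decision_index, observation = NULL) {
  as.integer((decision_index - 1L) %% 2L)
}

#' Constant (never-switching) meta policy
#'
#' @param task Task to stay on.
#' @return A meta policy function.
#' @export
constant_meta_policy <- function(task) {
  task <- as.integer(task)
  function(decision_index, observation = NULL) task
}

# ---------------------------------------------------------------------------
# Multitask engine: two environments advanced in lockstep, one attended.
# mt_reset/mt_decision expose a step-per-decision interface used both by
# run_multitask_episode() and by the meta-agent PPO trainer.

mt_reset <- function(env_configs, sub_policies, meta_cfg = meta_config(),
                     soc_cfg = soc_config(), seeds = NULL,
                     nfc_policies = NULL, compute_soc = TRUE) {
  stopifnot(length(env_configs) == 2L, length(sub_policies) == 2L)
  if (env_configs[[1]]$episode_length != env_configs[[2]]$episode_length) {
    stop("both subtasks must share the episode length", call. = FALSE)
  }
  if (env_configs[[1]]$episode_length %% meta_cfg$decision_interval != 0L) {
    stop("episode length must be a multiple of the decision interval",
         call. = FALSE)
  }
  states <- list(
    env_reset(env_configs[[1]], if (is.null(seeds)) NULL else seeds[1]),
    env_reset(env_configs[[2]], if (is.null(seeds)) NULL else seeds[2])
  )
  if (is.null(nfc_policies)) nfc_policies <- list(greedy_policy, greedy_policy)
  mt <- list(
    cfgs = env_configs, sub_policies = sub_policies, meta_cfg = meta_cfg,
    soc_cfg = soc_cfg, nfc_policies = nfc_policies,
    states = states, beliefs = states,
    soc = rep(soc_cfg$initial_soc, 2L), est = c(TRUE, TRUE),
    pe_active = 0, nfc_active = 0,
    active_prev = meta_cfg$initial_task, decision = 0L,
    n_decisions = env_configs[[1]]$episode_length %/%
      meta_cfg$decision_interval,
    compute_soc = isTRUE(compute_soc), done = FALSE
  )
  mt
}

mt_observation <- function(mt) {
  prev <- mt$active_prev
  if (mt$meta_cfg$observation_mode == "soc") {
    build_meta_observation(mt$soc[prev + 1L], mt$soc[2L - prev], prev,
                           mt$meta_cfg)
  } else {
    act_enc <- encode_sub_obs(mt$states[[prev + 1L]], mt$cfgs[[prev + 1L]])
    ina_enc <- encode_sub_obs(mt$beliefs[[2L - prev]], mt$cfgs[[2L - prev]])
    build_meta_observation(act_enc, ina_enc, prev, mt$meta_cfg)
  }
}

# Execute one meta decision: the chosen sub-policy emits k actions into its
# environment while the other receives k default actions. Returns the
# updated engine plus per-decision bookkeeping and (optionally) the
# per-frame log rows.
mt_decision <- function(mt, choice, log_frames = FALSE) {
  stopifnot(!mt$done, choice %in% c(0L, 1L))
  choice <- as.integer(choice)
  k <- mt$meta_cfg$decision_interval
  ai <- choice + 1L            # active index
  ii <- 2L - choice            # inactive index
  switch_flag <- choice != mt$active_prev

  # visible asteroid count in the task attended when the decision is taken
  visible_ctx <- visible_asteroids(mt$states[[mt$active_prev + 1L]],
                                   mt$cfgs[[mt$active_prev + 1L]])
  reward_soc <- if (mt$compute_soc) {
    meta_soc_reward(mt$soc[1L], mt$soc[2L], choice)
  } else NA_integer_

  st_a <- mt$states[[ai]]
  st_i <- mt$states[[ii]]
  cfg_a <- mt$cfgs[[ai]]
  cfg_i <- mt$cfgs[[ii]]
  pol_a <- mt$sub_policies[[ai]]
  rewards_a <- numeric(k)
  pe_last <- 0
  frames <- if (log_frames) vector("list", k) else NULL
  for (f in seq_len(k)) {
    a <- pol_a(st_a, cfg_a)
    pred_x <- predict_next(st_a, a, cfg_a)$state$ship_x
    out_a <- env_step(st_a, a, cfg_a)
    out_i <- env_step(st_i, 1L, cfg_i)
    pe_last <- prediction_error(out_a$state$ship_x, pred_x, mt$soc_cfg)
    rewards_a[f] <- out_a$reward
    if (log_frames) {
      cm <- matrix(0L, 2L, 2L)  # rows: task0/1, cols: collected/missed
      cm[choice + 1L, ] <- c(out_a$collected_now, out_a$missed_now)
      cm[2L - choice, ] <- c(out_i$collected_now, out_i$missed_now)
      frames[[f]] <- list(step = out_a$state$step, action = a,
                          realized_dx = out_a$realized_dx,
                          reward_active = out_a$reward, cm = cm)
    }
    st_a <- out_a$state
    st_i <- out_i$state
  }
  mt$states[[ai]] <- st_a
  mt$states[[ii]] <- st_i
  # the attended task is fully observed; the unattended belief advances
  # through the forward model under the default action
  mt$beliefs[[ai]] <- st_a
  mt$beliefs[[ii]] <- belief_propagation(mt$beliefs[[ii]], k, cfg_i)

  if (mt$compute_soc) {
    nfc <- need_for_control(st_a, cfg_a, mt$soc_cfg,
                            optimal_policy = mt$nfc_policies[[ai]])
    mt$soc[ai] <- compose_soc(pe_last, nfc)
    mt$est[ai] <- FALSE
    mt$soc[ii] <- decay_inactive(mt$soc[ii], mt$soc_cfg)
    mt$est[ii] <- TRUE
    mt$pe_active <- pe_last
    mt$nfc_active <- nfc
  }
  mt$active_prev <- choice
  mt$decision <- mt$decision + 1L
  mt$done <- mt$decision >= mt$n_decisions
  list(mt = mt, choice = choice, switch = switch_flag,
       reward_active = active_reward(rewards_a), reward_soc = reward_soc,
       visible_ctx = visible_ctx, frames = frames)
}

#' Run one multitask episode under a meta policy
#'
#' Runs the two subtask environments in lockstep for one full episode
#' (`episode_length / decision_interval` meta decisions). At each decision
#' the meta policy picks the task to attend; that task's sub-policy emits
#' `decision_interval` actions into its environment while the other
#' environment receives the default action. The attended task's SoC is
#' recomputed from its latest prediction error and need for control; the
#' unattended task's estimate decays once per decision.
#'
#' @param meta_policy Function `(decision_index, observation) -> task`
#'   (e.g. [switch_every_frame_policy()], [constant_meta_policy()], or a
#'   trained checkpoint's [as_meta_policy()]).
#' @param sub_policies List of two sub-policies, one per task.
#' @param env_configs List of two [env_config()]s.
#' @param meta_cfg A [meta_config()].
#' @param soc_cfg A [soc_config()].
#' @param seeds Optional integer pair seeding the two world generations.
#' @param nfc_policies Optional list of two policies used as the "optimal"
#'   trajectory of the need-for-control rollouts (default greedy oracle).
#' @param compute_soc Compute and log SoC components (disable to speed up
#'   runs whose meta policy needs neither SoC observations nor SoC reward).
#' @return An `episode_trace` tibble with one row per frame and a
#'   per-decision tibble in `attr(, "decisions")`; metadata (configs,
#'   seeds) in further attributes. See [episode_decisions()].
#' @export
run_multitask_episode <- function(meta_policy, sub_policies, env_configs,
                                  meta_cfg = meta_config(),
                                  soc_cfg = soc_config(),
                                  seeds = NULL, nfc_policies = NULL,
                                  compute_soc = TRUE) {
  mt <- mt_reset(env_configs, sub_policies, meta_cfg, soc_cfg, seeds,
                 nfc_policies, compute_soc)
  k <- meta_cfg$decision_interval
  nd <- mt$n_decisions
  n <- nd * k
  frame_cols <- list(step = integer(n), decision = integer(n),
                     active_task = integer(n), action = integer(n),
                     realized_dx = integer(n), reward_active = numeric(n),
                     collected_now_0 = integer(n), missed_now_0 = integer(n),
                     collected_now_1 = integer(n), missed_now_1 = integer(n),
                     soc_task0 = numeric(n), soc_task1 = numeric(n),
                     soc_is_estimate_0 = logical(n),
                     soc_is_estimate_1 = logical(n))
  dec <- list(decision = integer(nd), choice = integer(nd),
              switch = logical(nd), reward_active = numeric(nd),
              reward_soc = numeric(nd), visible_ctx = integer(nd),
              pe_active = numeric(nd), nfc_active = numeric(nd),
              soc_task0 = numeric(nd), soc_task1 = numeric(nd),
              in_free_span = logical(nd))
  spans <- env_configs[[1]]$asteroid_free_spans
  for (d in seq_len(nd)) {
    obs <- mt_observation(mt)
    soc_before <- mt$soc
    est_before <- mt$est
    choice <- as.integer(meta_policy(d, obs))
    step0 <- (d - 1L) * k + 1L
    res <- mt_decision(mt, choice, log_frames = TRUE)
    mt <- res$mt
    idx <- step0:(step0 + k - 1L)
    frame_cols$step[idx] <- vapply(res$frames, `[[`, integer(1), "step")
    frame_cols$decision[idx] <- d
    frame_cols$active_task[idx] <- choice
    frame_cols$action[idx] <- vapply(res$frames, `[[`, integer(1), "action")
    frame_cols$realized_dx[idx] <-
      vapply(res$frames, `[[`, integer(1), "realized_dx")
    frame_cols$reward_active[idx] <-
      vapply(res$frames, `[[`, numeric(1), "reward_active")
    cm <- lapply(res$frames, `[[`, "cm")
    frame_cols$collected_now_0[idx] <- vapply(cm, function(m) m[1, 1], 0L)
    frame_cols$missed_now_0[idx] <- vapply(cm, function(m) m[1, 2], 0L)
    frame_cols$collected_now_1[idx] <- vapply(cm, function(m) m[2, 1], 0L)
    frame_cols$missed_now_1[idx] <- vapply(cm, function(m) m[2, 2], 0L)
    frame_cols$soc_task0[idx] <- soc_before[1L]
    frame_cols$soc_task1[idx] <- soc_before[2L]
    frame_cols$soc_is_estimate_0[idx] <- est_before[1L]
    frame_cols$soc_is_estimate_1[idx] <- est_before[2L]
    dec$decision[d] <- d
    dec$choice[d] <- choice
    dec$switch[d] <- res$switch
    dec$reward_active[d] <- res$reward_active
    dec$reward_soc[d] <- as.numeric(res$reward_soc)
    dec$visible_ctx[d] <- res$visible_ctx
    dec$pe_active[d] <- mt$pe_active
    dec$nfc_active[d] <- mt$nfc_active
    dec$soc_task0[d] <- soc_before[1L]
    dec$soc_task1[d] <- soc_before[2L]
    dec$in_free_span[d] <- any(vapply(
      spans, function(sp) step0 >= sp[1] && (step0 + k - 1L) <= sp[2],
      logical(1)))
  }
  trace <- tibble::as_tibble(frame_cols)
  class(trace) <- c("episode_trace", class(trace))
  attr(trace, "decisions") <- tibble::as_tibble(dec)
  attr(trace, "final_states") <- mt$states
  attr(trace, "env_configs") <- env_configs
  attr(trace, "meta_config") <- meta_cfg
  attr(trace, "seeds") <- seeds
  trace
}

#' Per-decision records of a multitask episode
#'
#' @param trace An `episode_trace` from [run_multitask_episode()].
#' @return Tibble with one row per meta decision: chosen task, switch flag,
#'   aggregated active reward, SoC reward, visible-asteroid context, SoC
#'   components, and whether the decision falls inside an asteroid-free
#'   span.
#' @export
episode_decisions <- function(trace) {
  dec <- attr(trace, "decisions")
  if (is.null(dec)) stop("not an episode_trace with decision records")
  dec
}
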