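#' Normalized prediction error
#'
#' Discrepancy between the realized and the forward-model-predicted ship
#' column, squashed into `[0, 1]` with a hyperbolic tangent:
#' `tanh(pe_slope * |actual - predicted|)`. With the default slope of 0.5 a
#' displacement of 4 columns already yields an error of ~0.964, i.e.
#' effectively total surprise. Input noise only perturbs the ship's
#' horizontal step size, so the error is a function of the ship column
#' alone.
#'
#' @param actual_x Realized ship column.
#' @param predicted_x Predicted ship column.
#' @param cfg A [soc_config()].
#' @return Prediction error in `[0, 1]`.
#' @export
prediction_error <- function(actual_x, predicted_x, cfg = soc_config()) {
  stopifnot(is.finite(actual_x), is.finite(predicted_x))
  tanh(cfg$pe_slope * abs(actual_x - predicted_x))
}

#' Lookahead reward sequence through the forward model
#'
#' Builds the reward sequence of an N-step lookahead trajectory: the last
#' realized reward followed by `horizon - 1` model-predicted rewards,
#' obtained by iteratively feeding the predicted state and the policy's
#' action back into the forward model. The rollout truncates at the
#' episode end.
#'
#' @param state Current `world_state` (lookahead starts here).
#' @param policy Function `(state, config) -> action`.
#' @param horizon Trajectory length N (>= 2).
#' @param config An [env_config()].
#' @param r_prev The last realized reward; defaults to the dense reward of
#'   `state`.
#' @return Numeric vector `(r_prev, r_hat_1, ..., r_hat_{N-1})`, possibly
#'   shorter when the episode end truncates the lookahead.
#' @export
soc_rollout <- function(state, policy, horizon, config, r_prev = NULL) {
  stopifnot(horizon >= 2)
  if (is.null(r_prev)) r_prev <- dense_reward(state, config)
  rewards <- numeric(horizon)
  rewards[1L] <- r_prev
  k <- 1L
  for (i in seq_len(horizon - 1L)) {
    if (state$step >= config$episode_length) break
    pred <- predict_next(state, policy(state, config), config)
    state <- pred$state
    k <- k + 1L
    rewards[k] <- pred$reward
  }
  rewards[seq_len(k)]
}

#' Discounted rollout return
#'
#' The first (realized) reward enters undiscounted; the k-th predicted
#' reward is weighted `gamma^k`.
#'
#' @param rewards Reward sequence from [soc_rollout()].
#' @param gamma Discount factor.
#' @return Numeric scalar.
#' @export
discounted_sum <- function(rewards, gamma = 0.9) {
  stopifnot(length(rewards) >= 1)
  sum(rewards * gamma^(seq_along(rewards) - 1L))
}

#' Need for control
#'
#' Compares the discounted lookahead returns of two imagined trajectories
#' from the current state: one steered by the optimal policy, one left to
#' the default action. Their gap, divided by `nfc_scale` and clamped to
#' `[0, 1]`, quantifies how much the task currently demands intervention;
#' on an asteroid-free field the two trajectories coincide and the need for
#' control is exactly 0. The gap is floored at 0 before scaling: an
#' idealized optimal policy never trails the default one, but a merely
#' trained stand-in can.
#'
#' @param state Current `world_state`.
#' @param config An [env_config()].
#' @param cfg A [soc_config()].
#' @param optimal_policy Policy for the controlled trajectory (defaults to
#'   [greedy_policy()]).
#' @param def_policy Policy for the uncontrolled trajectory (defaults to
#'   [default_policy()]).
#' @param r_prev Last realized reward shared by both trajectories.
#' @return Need for control in `[0, 1]`.
#' @export
need_for_control <- function(state, config, cfg = soc_config(),
                             optimal_policy = greedy_policy,
                             def_policy = default_policy,
                             r_prev = NULL) {
  if (is.null(r_prev)) r_prev <- dense_reward(state, config)
  rs_o <- discounted_sum(
    soc_rollout(state, optimal_policy, cfg$horizon, config, r_prev),
    cfg$gamma)
  rs_d <- discounted_sum(
    soc_rollout(state, def_policy, cfg$horizon, config, r_prev),
    cfg$gamma)
  min(max(rs_o - rs_d, 0) / cfg$nfc_scale, 1)
}

#' Compose the sense of control
#'
#' `SoC = 1 - (PE + NfC) / 2`: full control (1) with zero prediction error
#' and zero need for control, no control (0) when both saturate.
#'
#' @param pe Prediction error in `[0, 1]`.
#' @param nfc Need for control in `[0, 1]`.
#' @return SoC in `[0, 1]`.
#' @export
compose_soc <- function(pe, nfc) {
  if (any(pe < 0 | pe > 1) || any(nfc < 0 | nfc > 1)) {
    stop("pe and nfc must lie in [0, 1]", call. = FALSE)
  }
  1 - (pe + nfc) / 2
}

#' Decay the SoC estimate of an unattended task
#'
#' While a task is not attended its SoC cannot be measured; the estimate
#' carries the previous value forward, decremented by `phi` and floored at
#' zero. Residues below 1e-12 (floating-point leftovers of repeated
#' decrements) are snapped to zero so the floor is reached in exactly
#' `ceiling(soc / phi)` applications.
#'
#' @param prev_soc Previous SoC (or estimate) in `[0, 1]`.
#' @param cfg A [soc_config()].
#' @return Decayed estimate in `[0, 1]`.
#' @export
decay_inactive <- function(prev_soc, cfg = soc_config()) {
  stopifnot(prev_soc >= 0, prev_soc <= 1)
  out <- prev_soc - cfg$phi
  if (out < 1e-12) 0 else out
}

#' SoC-difference reward for the meta-agent
#'
#' +1 for choosing the task whose SoC is strictly lower (the one sensed as
#' less well under control, hence needing attention), -1 for choosing the
#' higher-SoC task, 0 on ties.
#'
#' @param soc_task0,soc_task1 SoC values of the two tasks.
#' @param chosen Chosen task, 0 or 1.
#' @return Integer in -1:1.
#' @export
meta_soc_reward <- function(soc_task0, soc_task1, chosen) {
  stopifnot(chosen %in% c(0L, 1L),
            soc_task0 >= 0, soc_task0 <= 1, soc_task1 >= 0, soc_task1 <= 1)
  if (soc_task0 == soc_task1) return(0L)
  lower <- if (soc_task0 < soc_task1) 0L else 1L
  if (chosen == lower) 1L else -1L
}
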