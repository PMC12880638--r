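#' One-step forward model
#'
#' Deterministic, noise-unaware predictor of the next world state and its
#' dense reward. The ship's column moves by exactly the unit displacement
#' the action commands (clipped at the walls) and every entity advances one
#' row, mirroring the environment's time progression; collection events are
#' resolved with the environment's rule so that multi-step rollouts remain
#' consistent. The model consumes no randomness and is exact whenever input
#' noise is off.
#'
#' @param state A `world_state`.
#' @param action 0 (left), 1 (no steering) or 2 (right).
#' @param config An [env_config()].
#' @return A list (`prediction`): `state` (predicted `world_state`) and
#'   `reward` (dense reward of the predicted state).
#' @export
predict_next <- function(state, action, config) {
  stopifnot(action %in% c(0L, 1L, 2L))
  dx <- c(-1L, 0L, 1L)[action + 1L]
  new_x <- min(max(state$ship_x + dx, 1L), config$corridor_width)
  new_step <- state$step + 1L
  mid <- world_state(new_x, new_step, state$ast_col, state$ast_row,
                     state$ast_status, config)
  reward <- dense_reward(mid, config, include_current = TRUE)
  status <- state$ast_status
  hit <- which(status == 0L & state$ast_row == new_step)
  if (length(hit)) {
    got <- state$ast_col[hit] == new_x
    status[hit[got]] <- 1L
    status[hit[!got]] <- 2L
  }
  nxt <- world_state(new_x, new_step, state$ast_col, state$ast_row, status,
                     config)
  list(state = nxt, reward = reward)
}

#' Propagate a belief about an unattended task
#'
#' Iterates the forward model from the last observed state, feeding it the
#' default (no-steer) action for `elapsed_steps` steps. Because the default
#' action is never perturbed by input noise, the believed ship column never
#' drifts from the truth while a task is unattended.
#'
#' @param state Last observed `world_state` of the inactive task.
#' @param elapsed_steps Number of environment steps since that observation.
#' @param config An [env_config()].
#' @return The believed `world_state` after `elapsed_steps` steps.
#' @export
belief_propagation <- function(state, elapsed_steps, config) {
  stopifnot(elapsed_steps >= 0)
  for (i in seq_len(elapsed_steps)) {
    state <- predict_next(state, 1L, config)$state
  }
  state
}
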