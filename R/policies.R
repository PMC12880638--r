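#' Default (no-steer) policy
#'
#' The action executed in a task that is not being attended to: no steering
#' (action 1). Under it the ship's column never changes, so an unattended
#' task simply drifts forward in time.
#'
#' @param state A `world_state` (ignored).
#' @param config An [env_config()] (ignored).
#' @return Action 1.
#' @export
default_policy <- function(state, config) 1L

#' Greedy steering oracle
#'
#' Deterministic reference policy: steer one column toward the nearest
#' visible pending asteroid (smallest rows-to-go; ties broken by smaller
#' horizontal offset, then toward the corridor centre). With nothing
#' visible it emits the default no-steer action, so on an asteroid-free
#' field it coincides with [default_policy()]. Serves both as the "optimal
#' policy" of the need-for-control rollout and as a training-free success
#' rate reference.
#'
#' @param state A `world_state`.
#' @param config An [env_config()].
#' @return Action in 0:2.
#' @export
greedy_policy <- function(state, config) {
  vis <- visible_relative(state, config)
  if (!length(vis$dy)) return(1L)
  ord <- order(vis$dy, abs(vis$dx),
               abs(vis$col - (config$corridor_width + 1) / 2))
  target_dx <- vis$dx[ord[1L]]
  if (target_dx < 0L) 0L else if (target_dx > 0L) 2L else 1L
}

#' Asteroid-dodging policy
#'
#' Scripted controller that avoids every asteroid: whenever the next
#' asteroid row would be reached at the ship's column, it steps aside
#' (toward the side with more room). Useful for constructing worst-case
#' (all-missed) episodes.
#'
#' @inheritParams greedy_policy
#' @return Action in 0:2.
#' @export
dodge_policy <- function(state, config) {
  dy <- state$ast_row - state$step
  nxt <- which(state$ast_status == 0L & dy == 1L)
  if (!length(nxt)) return(1L)
  cols <- state$ast_col[nxt]
  if (!any(cols == state$ship_x)) return(1L)
  # step to a free adjacent column; prefer the side with more corridor room
  left_ok <- state$ship_x > 1L && !any(cols == state$ship_x - 1L)
  right_ok <- state$ship_x < config$corridor_width &&
    !any(cols == state$ship_x + 1L)
  if (left_ok && right_ok) {
    if (state$ship_x <= (config$corridor_width + 1L) / 2) 2L else 0L
  } else if (right_ok) 2L else if (left_ok) 0L else 1L
}
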