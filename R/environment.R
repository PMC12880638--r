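#' Generate a fresh Collect Asteroids world
#'
#' Places `asteroid_count` asteroids uniformly over the playable columns and
#' over the rows outside the asteroid-free spans (plus their visibility
#' margin), at most one asteroid per `min_row_gap` rows. The ship starts at
#' the central column. Uses R's global random number generator; seed it (or
#' use [env_reset()]) for reproducible layouts.
#'
#' @param config An [env_config()].
#' @return A `world_state`: list with `ship_x`, `step`, `ship_row`
#'   (`episode_length - step`, decremented every step), integer vectors
#'   `ast_col`, `ast_row` and `ast_status` (0 pending, 1 collected,
#'   2 missed).
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "env_config"))
  rows <- eligible_rows(config)
  n <- config$asteroid_count
  g <- config$min_row_gap
  if (g == 1L) {
    ast_row <- sample(rows, n)
  } else {
    # greedy spaced placement over a shuffled candidate list
    cand <- sample(rows)
    ast_row <- integer(0)
    for (r in cand) {
      if (length(ast_row) == n) break
      if (!length(ast_row) || min(abs(ast_row - r)) >= g) {
        ast_row <- c(ast_row, r)
      }
    }
    if (length(ast_row) < n) {
      stop("could not place ", n, " asteroids with min_row_gap = ", g,
           call. = FALSE)
    }
  }
  ast_row <- sort(as.integer(ast_row))
  world_state(
    ship_x = as.integer(ceiling(config$corridor_width / 2)),
    step = 0L,
    ast_col = sample.int(config$corridor_width, n, replace = TRUE),
    ast_row = ast_row,
    ast_status = integer(n),
    config = config
  )
}

world_state <- function(ship_x, step, ast_col, ast_row, ast_status, config) {
  structure(list(ship_x = as.integer(ship_x),
                 step = as.integer(step),
                 ship_row = config$episode_length - as.integer(step),
                 ast_col = as.integer(ast_col),
                 ast_row = as.integer(ast_row),
                 ast_status = as.integer(ast_status)),
            class = "world_state")
}

#' @export
print.world_state <- function(x, ...) {
  cat("<world_state> step ", x$step, ", ship at column ", x$ship_x,
      "; asteroids pending/collected/missed: ",
      sum(x$ast_status == 0L), "/", sum(x$ast_status == 1L), "/",
      sum(x$ast_status == 2L), "\n", sep = "")
  invisible(x)
}

#' Reset an environment to the start of a new episode
#'
#' @param config An [env_config()].
#' @param seed Optional integer seed applied before world generation.
#' @return A `world_state` at step 0.
#' @export
env_reset <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  generate_world(config)
}

#' Perturb a steering move with rounded Gaussian input noise
#'
#' When input noise is enabled, a draw from N(noise_mean, noise_variance)
#' is added to the intended unit move and the sum is rounded to the nearest
#' integer column displacement (positions are discrete); the result is
#' clipped at the walls later, by [env_step()]. With noise disabled the
#' intended move is returned unchanged.
#'
#' @param intended_dx Integer, -1 (left) or +1 (right).
#' @param config An [env_config()].
#' @return Integer realized displacement.
#' @export
apply_input_noise <- function(intended_dx, config) {
  stopifnot(intended_dx %in% c(-1L, 1L))
  if (!config$input_noise) return(as.integer(intended_dx))
  eps <- stats::rnorm(1L, mean = config$noise_mean,
                      sd = sqrt(config$noise_variance))
  as.integer(round(intended_dx + eps))
}

#' Advance the world by one step
#'
#' The ship first moves horizontally by the (possibly noise-perturbed)
#' displacement implied by the action, clipped at the walls, and descends
#' one row (`ship_row` decreases by 1). Any pending asteroid whose row is
#' reached at the new step is then resolved: collected when its column
#' matches the ship's, missed otherwise. The reward follows the configured
#' reward mode.
#'
#' @param state A `world_state`.
#' @param action 0 (left), 1 (no steering) or 2 (right).
#' @param config An [env_config()].
#' @return A list (`step_outcome`): `state` (next `world_state`), `reward`,
#'   `collected_now`, `missed_now`, `realized_dx`, `done`.
#' @export
env_step <- function(state, action, config) {
  if (state$step >= config$episode_length) {
    stop("episode is over; reset the environment", call. = FALSE)
  }
  stopifnot(action %in% c(0L, 1L, 2L))
  intended <- c(-1L, 0L, 1L)[action + 1L]
  realized <- if (action == 1L) 0L else apply_input_noise(intended, config)
  new_x <- min(max(state$ship_x + realized, 1L), config$corridor_width)
  new_step <- state$step + 1L
  # transition reward is read off the moved-but-unresolved state, so the
  # asteroid reached at this step still contributes to the dense field
  mid <- world_state(new_x, new_step, state$ast_col, state$ast_row,
                     state$ast_status, config)
  status <- state$ast_status
  hit <- which(status == 0L & state$ast_row == new_step)
  collected_now <- 0L
  missed_now <- 0L
  if (length(hit)) {
    got <- state$ast_col[hit] == new_x
    status[hit[got]] <- 1L
    status[hit[!got]] <- 2L
    collected_now <- sum(got)
    missed_now <- sum(!got)
  }
  nxt <- world_state(new_x, new_step, state$ast_col, state$ast_row, status,
                     config)
  reward <- if (config$reward_mode == "sparse") {
    sparse_reward(collected_now, missed_now, config)
  } else {
    dense_reward(mid, config, include_current = TRUE)
  }
  list(state = nxt, reward = reward,
       collected_now = as.integer(collected_now),
       missed_now = as.integer(missed_now),
       realized_dx = realized,
       done = new_step == config$episode_length)
}

# Pending asteroids within the visibility window, as (dy, dx) relative to
# the ship. dy in [1, window] rows ahead; with include_current also dy = 0,
# the row being resolved at the present step.
visible_relative <- function(state, config, include_current = FALSE) {
  dy <- state$ast_row - state$step
  lo <- if (include_current) 0L else 1L
  keep <- state$ast_status == 0L & dy >= lo & dy <= config$window
  list(dy = dy[keep], dx = state$ast_col[keep] - state$ship_x,
       col = state$ast_col[keep])
}

#' Number of pending asteroids currently visible
#'
#' @inheritParams env_step
#' @return Integer count of pending asteroids within the visibility window.
#' @export
visible_asteroids <- function(state, config) {
  vis <- visible_relative(state, config)
  length(vis$dy)
}

#' Dense shaping reward
#'
#' The positional state is viewed as an occupancy image of the visibility
#' window; a Gaussian blur (sd `blur_sigma` cells) spreads each pending
#' asteroid's intensity, and the reward reads the blurred value at the
#' ship's cell. A distance term, decreasing linearly in the horizontal
#' offset between the ship and the nearest incoming asteroid, promotes
#' early alignment. Both components are normalized to `[0, 1]`, weighted
#' equally, and scaled by `reward_scale`. With no asteroid in view the
#' reward is the background value, 0.
#'
#' During a transition ([env_step()], [predict_next()]) the reward is
#' evaluated at the post-move ship position but before the current row's
#' asteroid is resolved (`include_current = TRUE`), so that arriving
#' aligned on an asteroid's cell is itself maximally rewarded rather than
#' the asteroid vanishing from the reward field at the moment of
#' collection.
#'
#' @inheritParams env_step
#' @param include_current Also count a still-pending asteroid on the
#'   ship's own row (used for transition rewards).
#' @return Non-negative numeric reward.
#' @export
dense_reward <- function(state, config, include_current = FALSE) {
  vis <- visible_relative(state, config, include_current)
  if (!length(vis$dy)) return(0)
  s2 <- 2 * config$blur_sigma^2
  blur <- sum(exp(-(vis$dx^2 + vis$dy^2) / s2))
  blur01 <- min(blur, 1)
  nearest <- which.min(vis$dy)
  dist01 <- 1 - abs(vis$dx[nearest]) / (config$corridor_width - 1L)
  config$reward_scale * 0.5 * (blur01 + dist01)
}

#' Sparse event reward
#'
#' `+m` per asteroid collected this step, `-m` per asteroid missed, 0
#' otherwise, with `m = 100 / asteroid_count`; an episode in which every
#' asteroid is collected therefore totals +100, and -100 when all are
#' missed.
#'
#' @param collected_now,missed_now Event counts for the current step.
#' @param config An [env_config()].
#' @return Numeric reward.
#' @export
sparse_reward <- function(collected_now, missed_now, config) {
  m <- 100 / config$asteroid_count
  m * collected_now - m * missed_now
}

#' Success rate of a finished episode
#'
#' @param state A `world_state` at the episode end.
#' @param config An [env_config()].
#' @return Collected asteroids divided by the asteroid count, in `[0, 1]`.
#' @export
success_rate <- function(state, config) {
  if (state$step < config$episode_length) {
    stop("success_rate is defined at episode end only", call. = FALSE)
  }
  sum(state$ast_status == 1L) / config$asteroid_count
}

#' Render the visibility window as an occupancy grid
#'
#' @inheritParams env_step
#' @return Integer matrix with `window + 1` rows (the ship's row first,
#'   then one row per step of lookahead) and `corridor_width + 2` columns
#'   (walls at both edges). Cell codes: 0 empty, 1 asteroid, 2 ship,
#'   3 wall.
#' @export
render_occupancy_grid <- function(state, config) {
  grid <- matrix(0L, nrow = config$window + 1L,
                 ncol = config$corridor_width + 2L)
  grid[, 1L] <- 3L
  grid[, ncol(grid)] <- 3L
  vis <- visible_relative(state, config)
  if (length(vis$dy)) {
    grid[cbind(vis$dy + 1L, vis$col + 1L)] <- 1L
  }
  grid[1L, state$ship_x + 1L] <- 2L
  grid
}

#' Replay a fixed action sequence and log a per-step trace
#'
#' Convenience runner for a single subtask: applies `policy` (a function
#' `(state, config) -> action`) for a full episode and returns the trace as
#' a tibble, one row per step.
#'
#' @param config An [env_config()].
#' @param policy Function mapping `(state, config)` to an action in 0:2.
#' @param seed Optional seed for [env_reset()].
#' @return A tibble with columns `step`, `ship_x`, `action`, `realized_dx`,
#'   `reward`, `collected_now`, `missed_now`, plus attributes
#'   `final_state` and `config`.
#' @export
run_episode <- function(config, policy, seed = NULL) {
  state <- env_reset(config, seed)
  n <- config$episode_length
  step <- integer(n); ship_x <- integer(n); act <- integer(n)
  rdx <- integer(n); rew <- numeric(n); coll <- integer(n); miss <- integer(n)
  for (t in seq_len(n)) {
    a <- policy(state, config)
    out <- env_step(state, a, config)
    step[t] <- out$state$step; ship_x[t] <- out$state$ship_x
    act[t] <- a; rdx[t] <- out$realized_dx; rew[t] <- out$reward
    coll[t] <- out$collected_now; miss[t] <- out$missed_now
    state <- out$state
  }
  trace <- tibble::tibble(step = step, ship_x = ship_x, action = act,
                          realized_dx = rdx, reward = rew,
                          collected_now = coll, missed_now = miss)
  attr(trace, "final_state") <- state
  attr(trace, "config") <- config
  trace
}
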