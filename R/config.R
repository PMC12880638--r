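#' Configuration for one Collect Asteroids subtask
#'
#' Builds the configuration object describing a single vertical-corridor
#' asteroid-collection task. Difficulty fixes the asteroid count (14 easy,
#' 30 hard); optional input noise perturbs every executed steering move by a
#' rounded Gaussian offset with mean 0 and variance 1.5.
#'
#' The corridor has `corridor_width` playable columns (1-based, flanked by
#' walls); the ship sees `window` rows ahead. Episodes last `episode_length`
#' steps. `asteroid_free_spans` are step intervals kept free of asteroids;
#' asteroid placement additionally keeps a trailing margin of
#' `placement_margin` rows after each span so that, while the span lasts,
#' no asteroid is visible nor perceivable by any state of a
#' need-for-control lookahead rollout launched within the span.
#'
#' @param difficulty `"easy"` (14 asteroids) or `"hard"` (30 asteroids).
#' @param input_noise Logical; add rounded Gaussian noise to steering moves.
#' @param episode_length Number of steps per episode (default 470).
#' @param corridor_width Number of playable columns between the walls.
#' @param window Visibility window: how many rows ahead are observable.
#' @param asteroid_free_spans List of two-element integer vectors
#'   `c(first_step, last_step)`; defaults to 40 steps at the episode start
#'   and 40 steps centred on the episode midpoint.
#' @param reward_mode `"dense"` (Gaussian-blurred occupancy plus distance
#'   shaping) or `"sparse"` (+/- 100/N on collection/miss events).
#' @param noise_mean,noise_variance Moments of the steering noise.
#' @param min_row_gap Minimum row spacing between asteroids (1 = one
#'   asteroid per row, the default).
#' @param placement_margin Rows after each asteroid-free span kept clear of
#'   asteroids; defaults to `window + 9`, one visibility window plus the
#'   reach of the default 10-step lookahead rollout.
#' @param reward_scale Peak value of the dense per-step reward.
#' @param blur_sigma Standard deviation (in cells) of the Gaussian blur
#'   applied to the occupancy representation for the dense reward.
#'
#' @return An object of class `env_config` (a named list).
#' @examples
#' cfg <- env_config("easy")
#' cfg$asteroid_count
#' @export
env_config <- function(difficulty = c("easy", "hard"),
                       input_noise = FALSE,
                       episode_length = 470L,
                       corridor_width = 9L,
                       window = 10L,
                       asteroid_free_spans = NULL,
                       reward_mode = c("dense", "sparse"),
                       noise_mean = 0,
                       noise_variance = 1.5,
                       min_row_gap = 1L,
                       placement_margin = NULL,
                       reward_scale = 100,
                       blur_sigma = 1.0) {
  difficulty <- match.arg(difficulty)
  reward_mode <- match.arg(reward_mode)
  episode_length <- as.integer(episode_length)
  corridor_width <- as.integer(corridor_width)
  window <- as.integer(window)
  stopifnot(episode_length > 0, corridor_width >= 3, window >= 1,
            noise_variance > 0, min_row_gap >= 1, reward_scale > 0,
            blur_sigma > 0)
  if (is.null(asteroid_free_spans)) {
    mid <- floor(episode_length / 2L)
    asteroid_free_spans <- list(
      c(1L, 40L),
      c(mid - 19L, mid + 20L)
    )
  }
  if (is.null(placement_margin)) placement_margin <- window + 9L
  asteroid_free_spans <- lapply(asteroid_free_spans, function(sp) {
    sp <- as.integer(sp)
    stopifnot(length(sp) == 2L, sp[1] >= 1L, sp[2] >= sp[1],
              sp[2] <= episode_length)
    sp
  })
  cfg <- structure(list(
    difficulty = difficulty,
    asteroid_count = if (difficulty == "easy") 14L else 30L,
    input_noise = isTRUE(input_noise),
    noise_mean = noise_mean,
    noise_variance = noise_variance,
    episode_length = episode_length,
    corridor_width = corridor_width,
    window = window,
    asteroid_free_spans = asteroid_free_spans,
    reward_mode = reward_mode,
    min_row_gap = as.integer(min_row_gap),
    placement_margin = as.integer(placement_margin),
    reward_scale = reward_scale,
    blur_sigma = blur_sigma
  ), class = "env_config")
  n_eligible <- length(eligible_rows(cfg))
  if (n_eligible < cfg$asteroid_count * cfg$min_row_gap) {
    stop("corridor cannot host ", cfg$asteroid_count,
         " asteroids under the placement constraints", call. = FALSE)
  }
  cfg
}

#' @export
print.env_config <- function(x, ...) {
  cat("<env_config> ", x$difficulty, " (", x$asteroid_count, " asteroids), ",
      "noise=", x$input_noise, ", ", x$episode_length, " steps, width ",
      x$corridor_width, ", reward=", x$reward_mode, "\n", sep = "")
  invisible(x)
}

# Rows where asteroids may be placed: everything outside the asteroid-free
# spans plus their trailing margin, so the spans are experienced as phases
# with no visible (or rollout-perceivable) asteroids at all.
eligible_rows <- function(config) {
  rows <- seq_len(config$episode_length)
  for (sp in config$asteroid_free_spans) {
    rows <- setdiff(rows, seq(sp[1], min(sp[2] + config$placement_margin,
                                         config$episode_length)))
  }
  rows
}

#' Parameters of the sense-of-control computation
#'
#' @param horizon Rollout length N used by the need-for-control lookahead
#'   (the last realized reward followed by N - 1 model-predicted rewards).
#' @param gamma Discount weighting the predicted rewards in the rollout sum.
#' @param phi Per-decision decay applied to the inactive task's SoC estimate.
#' @param nfc_scale Normalizer dividing the optimal-minus-default rollout
#'   return gap before clamping to `[0, 1]`.
#' @param pe_slope Slope inside the `tanh` that normalizes the prediction
#'   error; 0.5 maps a 4-column miss to an error of ~0.96.
#' @param initial_soc SoC assigned to a task before its first measurement.
#'
#' @return An object of class `soc_config`.
#' @export
soc_config <- function(horizon = 10L, gamma = 0.9, phi = 0.1,
                       nfc_scale = 100, pe_slope = 0.5, initial_soc = 1.0) {
  stopifnot(horizon >= 2, gamma > 0, gamma < 1, phi > 0, nfc_scale > 0,
            pe_slope > 0, initial_soc >= 0, initial_soc <= 1)
  structure(list(horizon = as.integer(horizon), gamma = gamma, phi = phi,
                 nfc_scale = nfc_scale, pe_slope = pe_slope,
                 initial_soc = initial_soc),
            class = "soc_config")
}

#' Configuration of the meta-agent (task-switching) level
#'
#' The four learnable meta-agent variants arise from crossing the
#' observation mode (positions vs. SoC values) with the reward mode (active
#' sub-agent reward vs. SoC-difference reward):
#' `world_state`+`active` = "no_soc", `soc`+`active` = "soc_as_observation",
#' `world_state`+`soc` = "soc_as_reward", `soc`+`soc` = "soc".
#'
#' @param observation_mode `"world_state"` or `"soc"`.
#' @param reward_mode `"active"` or `"soc"`.
#' @param decision_interval Frames between meta decisions (default 5).
#' @param initial_task Task (0 or 1) considered active before the first
#'   decision; the reference against which the first switch is counted.
#'
#' @return An object of class `meta_config` with derived `agent_label`.
#' @export
meta_config <- function(observation_mode = c("world_state", "soc"),
                        reward_mode = c("active", "soc"),
                        decision_interval = 5L,
                        initial_task = 1L) {
  observation_mode <- match.arg(observation_mode)
  reward_mode <- match.arg(reward_mode)
  stopifnot(decision_interval >= 1, initial_task %in% c(0L, 1L))
  label <- if (observation_mode == "world_state" && reward_mode == "active") {
    "no_soc"
  } else if (observation_mode == "soc" && reward_mode == "active") {
    "soc_as_observation"
  } else if (observation_mode == "world_state" && reward_mode == "soc") {
    "soc_as_reward"
  } else {
    "soc"
  }
  structure(list(observation_mode = observation_mode,
                 reward_mode = reward_mode,
                 decision_interval = as.integer(decision_interval),
                 initial_task = as.integer(initial_task),
                 agent_label = label),
            class = "meta_config")
}

#' Read an environment/block configuration from a YAML file
#'
#' Recognized keys: `difficulty`, `input_noise`, `episode_length`,
#' `corridor_width`, `seed`, `reward_mode`, `asteroid_free_spans` (list of
#' `[first, last]` pairs). Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `config` (an [env_config()]) and `seed`
#'   (integer or `NULL`).
#' @export
read_env_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("difficulty", "input_noise", "episode_length",
               "corridor_width", "seed", "reward_mode",
               "asteroid_free_spans")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  seed <- raw$seed
  raw$seed <- NULL
  if (!is.null(raw$asteroid_free_spans)) {
    raw$asteroid_free_spans <- lapply(raw$asteroid_free_spans, as.integer)
  }
  cfg <- do.call(env_config, raw)
  list(config = cfg, seed = if (is.null(seed)) NULL else as.integer(seed))
}
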