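# Shared fixtures, built in code.

# A hand-laid world: asteroids at known (row, col), ship centred.
fixed_world <- function(config, rows, cols, ship_x = NULL, step = 0L,
                        status = NULL) {
  if (is.null(ship_x)) ship_x <- ceiling(config$corridor_width / 2)
  if (is.null(status)) status <- integer(length(rows))
  soctask:::world_state(ship_x, step, cols, rows, status, config)
}

# An empty field (no asteroids at all) of the default geometry.
empty_world <- function(config, ship_x = NULL, step = 0L) {
  fixed_world(config, integer(0), integer(0), ship_x, step)
}

# Spaced-out placement that a greedy controller can always reach: row gaps
# of at least the corridor width.
reachable_cfg <- function(difficulty = "easy", ...) {
  env_config(difficulty, min_row_gap = 9L, reward_mode = "sparse", ...)
}

default_pair <- function(...) list(env_config("easy", ...), env_config("easy", ...))

greedy_subs <- list(greedy_policy, greedy_policy)
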