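test_that("world generation places the difficulty-determined asteroid count", {
  set.seed(1)
  st_e <- generate_world(env_config("easy"))
  st_h <- generate_world(env_config("hard"))
  expect_identical(sum(st_e$ast_status == 0L), 14L)
  expect_identical(sum(st_h$ast_status == 0L), 30L)
  expect_identical(st_e$step, 0L)
  expect_identical(st_e$ship_x, 5L)
})

test_that("generation is deterministic under a fixed seed and avoids free spans", {
  cfg <- env_config("hard")
  a <- env_reset(cfg, seed = 7)
  b <- env_reset(cfg, seed = 7)
  expect_identical(a, b)
  for (sp in cfg$asteroid_free_spans) {
    expect_false(any(a$ast_row >= sp[1] &
                     a$ast_row <= sp[2] + cfg$placement_margin))
  }
  expect_true(all(a$ast_col >= 1 & a$ast_col <= cfg$corridor_width))
  # one asteroid per row under the default spacing
  expect_false(any(duplicated(a$ast_row)))
})

test_that("an impossible placement request is a configuration error", {
  expect_error(env_config("hard", episode_length = 50L,
                          asteroid_free_spans = list(c(1L, 30L))),
               "cannot host")
})

test_that("steering moves, clips at walls, and descends one row per step", {
  cfg <- env_config("easy")
  st <- empty_world(cfg, ship_x = 5L)
  out <- env_step(st, 0L, cfg)
  expect_identical(out$state$ship_x, 4L)
  expect_identical(out$state$step, 1L)
  expect_identical(out$state$ship_row, st$ship_row - 1L)
  expect_identical(env_step(st, 1L, cfg)$state$ship_x, 5L)
  expect_identical(env_step(st, 2L, cfg)$state$ship_x, 6L)
  at_wall <- empty_world(cfg, ship_x = 1L)
  expect_identical(env_step(at_wall, 0L, cfg)$state$ship_x, 1L)
  at_right <- empty_world(cfg, ship_x = cfg$corridor_width)
  expect_identical(env_step(at_right, 2L, cfg)$state$ship_x,
                   cfg$corridor_width)
})

test_that("stepping past the episode end is a usage error", {
  cfg <- env_config("easy")
  st <- empty_world(cfg, step = cfg$episode_length)
  expect_error(env_step(st, 1L, cfg), "episode is over")
})

test_that("input noise is identity when disabled and rounded Gaussian when on", {
  cfg_off <- env_config("easy")
  expect_identical(apply_input_noise(1L, cfg_off), 1L)
  expect_identical(apply_input_noise(-1L, cfg_off), -1L)
  # noiseless steps consume no randomness
  set.seed(42); before <- .Random.seed
  env_step(empty_world(cfg_off), 0L, cfg_off)
  expect_identical(.Random.seed, before)
})

test_that("noise offsets match the rounded-Gaussian brute-force oracle", {
  cfg <- env_config("easy", input_noise = TRUE)
  set.seed(99)
  n <- 20000L
  drawn <- vapply(seq_len(n), function(i) apply_input_noise(1L, cfg) - 1L,
                  integer(1))
  oracle <- as.integer(round(1 + stats::rnorm(n, 0, sqrt(1.5))) - 1L)
  expect_lt(abs(mean(drawn) - mean(oracle)), 0.03)
  expect_lt(abs(stats::var(drawn) - stats::var(oracle)), 0.08)
  # distributional agreement over the pooled integer support
  support <- sort(unique(c(drawn, oracle)))
  tab <- rbind(tabulate(match(drawn, support), length(support)),
               tabulate(match(oracle, support), length(support)))
  keep <- colSums(tab) >= 10
  p <- suppressWarnings(stats::chisq.test(tab[, keep])$p.value)
  expect_gt(p, 0.001)
})

test_that("asteroid accounting is conserved at every step of an episode", {
  cfg <- env_config("hard", input_noise = TRUE)
  st <- env_reset(cfg, seed = 12)
  set.seed(12)
  n_res <- integer(0)
  for (t in seq_len(cfg$episode_length)) {
    out <- env_step(st, sample(0:2, 1L), cfg)
    st <- out$state
    expect_identical(sum(st$ast_status == 0L) + sum(st$ast_status == 1L) +
                       sum(st$ast_status == 2L), cfg$asteroid_count)
  }
  expect_true(out$done)
  expect_identical(sum(st$ast_status == 0L), 0L)  # all resolved at the end
})

test_that("noise-free episodes are reproducible trace-for-trace", {
  cfg <- env_config("easy")
  tr1 <- run_episode(cfg, greedy_policy, seed = 5)
  tr2 <- run_episode(cfg, greedy_policy, seed = 5)
  expect_identical(tr1, tr2)
  expect_identical(nrow(tr1), cfg$episode_length)
})

test_that("sparse rewards follow the 100/N event rule and total bounds", {
  cfg <- env_config("easy", reward_mode = "sparse")
  expect_equal(sparse_reward(1L, 0L, cfg), 100 / 14)
  expect_equal(sparse_reward(0L, 0L, cfg), 0)
  expect_equal(sparse_reward(0L, 2L, cfg), -200 / 14)
  for (diff in c("easy", "hard")) {
    rcfg <- reachable_cfg(diff)
    tr <- run_episode(rcfg, greedy_policy, seed = 3)
    expect_equal(sum(tr$reward), 100)
    expect_equal(success_rate(attr(tr, "final_state"), rcfg), 1)
    dcfg <- env_config(diff, reward_mode = "sparse")
    trd <- run_episode(dcfg, dodge_policy, seed = 3)
    expect_equal(sum(trd$reward), -100)
    expect_equal(success_rate(attr(trd, "final_state"), dcfg), 0)
  }
})

test_that("episode sparse totals stay within [-100, 100] for arbitrary play", {
  cfg <- env_config("easy", reward_mode = "sparse")
  set.seed(8)
  for (i in 1:3) {
    pol <- function(state, config) sample(0:2, 1L)
    tr <- run_episode(cfg, pol)
    expect_gte(sum(tr$reward), -100)
    expect_lte(sum(tr$reward), 100)
    sr <- success_rate(attr(tr, "final_state"), cfg)
    expect_gte(sr, 0); expect_lte(sr, 1)
  }
})

test_that("success rate is collected over total and defined only when done", {
  cfg <- env_config("hard")
  fin <- fixed_world(cfg, rows = seq_len(30), cols = rep(1L, 30),
                     step = cfg$episode_length,
                     status = c(rep(1L, 21L), rep(2L, 9L)))
  expect_equal(success_rate(fin, cfg), 0.7)
  mid <- fixed_world(cfg, rows = 1L, cols = 1L, step = 10L, status = 2L)
  expect_error(success_rate(mid, cfg), "episode end")
})

test_that("dense reward is zero on an empty field and peaks on alignment", {
  cfg <- env_config("easy")
  expect_equal(dense_reward(empty_world(cfg), cfg), 0)
  # single incoming asteroid: reward strictly decreases with |dx|,
  # checked by brute force over every ship column
  vals <- vapply(seq_len(cfg$corridor_width), function(x) {
    st <- fixed_world(cfg, rows = 3L, cols = 5L, ship_x = x)
    dense_reward(st, cfg)
  }, numeric(1))
  d <- abs(seq_len(cfg$corridor_width) - 5L)
  expect_true(all(diff(vals[order(d)]) <= 0))
  expect_identical(which.max(vals), 5L)
  expect_true(all(vals >= 0))
  # being on the asteroid's cell beats being adjacent, all else equal
  on <- dense_reward(fixed_world(cfg, 1L, 5L, ship_x = 5L), cfg,
                     include_current = TRUE)
  off <- dense_reward(fixed_world(cfg, 1L, 5L, ship_x = 4L), cfg,
                      include_current = TRUE)
  expect_gt(on, off)
})

test_that("occupancy grid has window geometry and conserves visible asteroids", {
  cfg <- env_config("easy")
  g0 <- render_occupancy_grid(empty_world(cfg), cfg)
  expect_identical(dim(g0), c(cfg$window + 1L, cfg$corridor_width + 2L))
  expect_identical(sum(g0 == 2L), 1L)          # one ship marker
  expect_true(all(g0[, 1] == 3L) && all(g0[, ncol(g0)] == 3L))
  expect_identical(sum(g0 == 1L), 0L)
  st <- env_reset(env_config("hard"), seed = 4)
  g <- render_occupancy_grid(st, env_config("hard"))
  expect_identical(sum(g == 1L), visible_asteroids(st, env_config("hard")))
})

test_that("YAML configuration round-trips through read_env_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(difficulty = "hard", input_noise = TRUE,
                        corridor_width = 9, seed = 11,
                        reward_mode = "sparse"), path)
  got <- read_env_config(path)
  expect_identical(got$config$difficulty, "hard")
  expect_true(got$config$input_noise)
  expect_identical(got$config$reward_mode, "sparse")
  expect_identical(got$seed, 11L)
  yaml::write_yaml(list(difficulty = "easy", bogus = 1), path)
  expect_error(read_env_config(path), "unknown config keys")
})
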