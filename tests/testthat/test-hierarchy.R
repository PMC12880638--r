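test_that("a multitask episode has the fixed decision cadence", {
  tr <- run_multitask_episode(switch_every_frame_policy, greedy_subs,
                              default_pair(), seeds = c(1, 2))
  dec <- episode_decisions(tr)
  expect_identical(nrow(dec), 94L)           # 470 / 5 decision points
  expect_identical(nrow(tr), 470L)
  expect_identical(tr$step, 1:470)
  # the active task changes only at decision boundaries
  changes <- which(diff(tr$active_task) != 0L)
  expect_true(all(changes %% 5L == 0L))
  # every frame is controlled by exactly one task; ratios partition
  expect_equal(engagement_ratio(tr, 0L) + engagement_ratio(tr, 1L), 1)
})

test_that("switch-every-frame realizes a switch at all 94 decisions, exactly", {
  for (s in 1:3) {
    tr <- run_multitask_episode(switch_every_frame_policy, greedy_subs,
                                default_pair(), seeds = c(s, s + 100))
    expect_identical(count_switches(tr), 94L)
    expect_equal(engagement_ratio(tr, 0L), 0.5)
    expect_equal(engagement_ratio(tr, 1L), 0.5)
  }
  # the toggle pattern starts at task 0: decisions 1,2,3 -> 0,1,0
  dec <- episode_decisions(tr)
  expect_identical(dec$choice[1:3], c(0L, 1L, 0L))
  # alternation gives each task exactly half the frames
  expect_identical(sum(tr$active_task == 0L), 235L)
})

test_that("a never-switching policy yields full engagement and no switches", {
  tr <- run_multitask_episode(constant_meta_policy(1L), greedy_subs,
                              default_pair(), seeds = c(3, 4))
  expect_identical(count_switches(tr), 0L)
  expect_equal(engagement_ratio(tr, 1L), 1)
  # staying on task 0 departs once from the initial reference task
  tr0 <- run_multitask_episode(constant_meta_policy(0L), greedy_subs,
                               default_pair(), seeds = c(3, 4))
  expect_identical(count_switches(tr0), 1L)
})

test_that("meta observations expose measured and estimated SoC correctly", {
  cfgs <- default_pair()
  scfg <- soc_config()
  mt <- soctask:::mt_reset(cfgs, greedy_subs, meta_config("soc", "soc"),
                           scfg, seeds = c(5, 6))
  obs0 <- soctask:::mt_observation(mt)
  expect_identical(obs0, c(scfg$initial_soc, scfg$initial_soc, 1))
  # three decisions on task 0: task 1's estimate decays once per decision
  for (d in 1:3) mt <- soctask:::mt_decision(mt, 0L)$mt
  expect_equal(mt$soc[2L],
               scfg$initial_soc - 3 * scfg$phi)
  expect_true(mt$est[2L])
  expect_false(mt$est[1L])
})

test_that("world-state observations carry an exact belief when noise is off", {
  cfgs <- default_pair()
  mt <- soctask:::mt_reset(cfgs, greedy_subs,
                           meta_config("world_state", "active"),
                           seeds = c(7, 8))
  for (d in 1:4) mt <- soctask:::mt_decision(mt, 0L)$mt
  expect_identical(mt$beliefs[[2L]], mt$states[[2L]])
  obs <- soctask:::mt_observation(mt)
  expect_identical(obs,
                   c(encode_sub_obs(mt$states[[1L]], cfgs[[1]]),
                     encode_sub_obs(mt$states[[2L]], cfgs[[2]]), 0))
})

test_that("SoC-mode meta rewards take values in {-1, 0, 1} only", {
  tr <- run_multitask_episode(switch_every_frame_policy, greedy_subs,
                              default_pair(), meta_config("soc", "soc"),
                              seeds = c(9, 10))
  dec <- episode_decisions(tr)
  expect_true(all(dec$reward_soc %in% c(-1, 0, 1)))
})

test_that("active reward aggregates the attended environment's rewards", {
  expect_equal(active_reward(numeric(5)), 0)
  expect_equal(active_reward(rep(1, 5)), 5)
  tr <- run_multitask_episode(constant_meta_policy(0L), greedy_subs,
                              default_pair(), seeds = c(11, 12))
  dec <- episode_decisions(tr)
  agg <- tapply(tr$reward_active, tr$decision, sum)
  expect_equal(as.numeric(agg[as.character(dec$decision)]),
               dec$reward_active)
})

test_that("exactly one task's SoC is an estimate after every decision", {
  tr <- run_multitask_episode(switch_every_frame_policy, greedy_subs,
                              default_pair(), seeds = c(13, 14))
  dec <- episode_decisions(tr)
  est <- cbind(tr$soc_is_estimate_0, tr$soc_is_estimate_1)
  # from the second decision on, the previous slice measured one task
  later <- tr$decision >= 2L
  expect_true(all(xor(est[later, 1], est[later, 2])))
  expect_true(all(tr$soc_task0 >= 0 & tr$soc_task0 <= 1))
  expect_true(all(tr$soc_task1 >= 0 & tr$soc_task1 <= 1))
})

test_that("noise-free episodes have zero prediction error throughout", {
  tr <- run_multitask_episode(switch_every_frame_policy, greedy_subs,
                              default_pair(), seeds = c(15, 16))
  dec <- episode_decisions(tr)
  expect_true(all(dec$pe_active == 0))
  # hence the freshly measured SoC (visible at the next decision for the
  # task just attended) is 1 - NfC / 2
  prev_choice <- dec$choice[-94]
  soc_next <- ifelse(prev_choice == 0L, dec$soc_task0[-1], dec$soc_task1[-1])
  expect_equal(soc_next, (1 - dec$nfc_active / 2)[-94])
})

test_that("input noise produces nonzero prediction errors", {
  cfgs <- list(env_config("easy", input_noise = TRUE),
               env_config("easy", input_noise = TRUE))
  set.seed(77)
  tr <- run_multitask_episode(switch_every_frame_policy, greedy_subs, cfgs,
                              seeds = c(17, 18))
  dec <- episode_decisions(tr)
  # greedy steers only when misaligned, so surprises are sparse but present
  expect_gt(mean(dec$pe_active > 0), 0)
  expect_true(all(dec$pe_active >= 0 & dec$pe_active <= 1))
  # a wall-hugging always-steer policy is surprised whenever the rounded
  # noise pulls the ship off the wall (about one frame in six)
  steer <- function(state, config) 2L
  set.seed(78)
  tr2 <- run_multitask_episode(switch_every_frame_policy,
                               list(steer, steer), cfgs, seeds = c(19, 20))
  dec2 <- episode_decisions(tr2)
  expect_gt(mean(dec2$pe_active > 0), 0.05)
})

test_that("mismatched episode lengths between the two tasks are rejected", {
  cfgs <- list(env_config("easy"),
               env_config("easy", episode_length = 235L,
                          asteroid_free_spans = list(c(1L, 20L))))
  expect_error(run_multitask_episode(switch_every_frame_policy, greedy_subs,
                                     cfgs, seeds = c(1, 2)),
               "episode length")
})

test_that("trace export writes frame, decision and metadata files", {
  tr <- run_multitask_episode(switch_every_frame_policy, greedy_subs,
                              default_pair(), seeds = c(19, 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path, block_id = "easy_easy_no")
  expect_true(file.exists(path))
  back <- utils::read.csv(path)
  expect_identical(nrow(back), 470L)
  dec_back <- utils::read.csv(sub("\\.csv$", "-decisions.csv", path))
  expect_identical(nrow(dec_back), 94L)
  meta <- yaml::read_yaml(sub("\\.csv$", "-meta.yaml", path))
  expect_identical(meta$block_id, "easy_easy_no")
})
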