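#' Enumerate the ten multitasking blocks
#'
#' Crossing the two tasks' difficulties (easy+easy, easy+hard, hard+hard)
#' with the input-noise placement (absent, in one task, in both; for the
#' mixed-difficulty family distinguishing noise in the easy vs. the hard
#' task) yields exactly ten configurations. When only one task of an
#' equal-difficulty pair carries noise, it is task one.
#'
#' @return Tibble with columns `block_id`, `difficulty_1`, `difficulty_2`,
#'   `noise_1`, `noise_2`, in canonical order.
#' @export
enumerate_blocks <- function() {
  tibble::tribble(
    ~block_id, ~difficulty_1, ~difficulty_2, ~noise_1, ~noise_2,
    "easy_easy_no", "easy", "easy", FALSE, FALSE,
    "easy_easy_yes-in-one-task", "easy", "easy", TRUE, FALSE,
    "easy_easy_yes", "easy", "easy", TRUE, TRUE,
    "easy_hard_no", "easy", "hard", FALSE, FALSE,
    "easy_hard_yes-in-easy-task", "easy", "hard", TRUE, FALSE,
    "easy_hard_yes-in-hard-task", "easy", "hard", FALSE, TRUE,
    "easy_hard_yes", "easy", "hard", TRUE, TRUE,
    "hard_hard_no", "hard", "hard", FALSE, FALSE,
    "hard_hard_yes-in-one-task", "hard", "hard", TRUE, FALSE,
    "hard_hard_yes", "hard", "hard", TRUE, TRUE
  )
}

#' Environment configurations of one block
#'
#' @param block_id A `block_id` from [enumerate_blocks()].
#' @param ... Further arguments passed to [env_config()] (geometry, reward
#'   mode, ...).
#' @return List of two [env_config()]s, tasks one and two.
#' @export
block_env_configs <- function(block_id, ...) {
  blocks <- enumerate_blocks()
  row <- blocks[blocks$block_id == block_id, ]
  if (nrow(row) != 1L) stop("unknown block id: ", block_id, call. = FALSE)
  list(env_config(row$difficulty_1, input_noise = row$noise_1, ...),
       env_config(row$difficulty_2, input_noise = row$noise_2, ...))
}

#' Engagement ratio
#'
#' Proportion of frames during which the given task was attended, relative
#' to the episode length. The two tasks' ratios sum to one.
#'
#' @param trace An `episode_trace`.
#' @param task Task index (0 = task one, the default; 1 = task two).
#' @return Ratio in `[0, 1]`.
#' @export
engagement_ratio <- function(trace, task = 0L) {
  mean(trace$active_task == task)
}

#' Number of task switches in an episode
#'
#' A decision counts as a switch when its chosen task differs from the
#' previously active one (the pre-episode reference task for the first
#' decision), so a policy toggling at every opportunity realizes one switch
#' per decision point.
#'
#' @param trace An `episode_trace`.
#' @return Integer switch count.
#' @export
count_switches <- function(trace) {
  sum(episode_decisions(trace)$switch)
}

#' Switching ratio at each decision index
#'
#' For each of the `episode_length / decision_interval` decision points,
#' the fraction of episodes in which a switch occurred there, with a flag
#' marking decisions inside the asteroid-free spans.
#'
#' @param traces List of `episode_trace`s.
#' @return Tibble with columns `decision`, `ratio`, `in_free_span`.
#' @export
switching_ratio_per_timestep <- function(traces) {
  stopifnot(length(traces) >= 1)
  decs <- lapply(traces, episode_decisions)
  sw <- vapply(decs, function(d) as.numeric(d$switch), numeric(nrow(decs[[1]])))
  tibble::tibble(decision = decs[[1]]$decision,
                 ratio = rowMeans(matrix(sw, nrow = nrow(decs[[1]]))),
                 in_free_span = decs[[1]]$in_free_span)
}

#' Visible asteroids at switch vs. non-switch decisions
#'
#' Compares the circumstances of task-switching and non-switching decisions
#' by the number of asteroids visible in the attended task at the moment of
#' the decision. For an always-switching policy the non-switch group is
#' empty and reported as absent (`NA` mean, n = 0).
#'
#' @param traces List of `episode_trace`s.
#' @return Tibble with one row per context (`"switch"`, `"non_switch"`):
#'   mean, sd and number of contributing decisions.
#' @export
asteroids_at_switch <- function(traces) {
  stopifnot(length(traces) >= 1)
  dec <- dplyr::bind_rows(lapply(traces, episode_decisions))
  dec |>
    dplyr::mutate(context = ifelse(.data$switch, "switch", "non_switch")) |>
    dplyr::group_by(.data$context) |>
    dplyr::summarise(mean = mean(.data$visible_ctx),
                     sd = stats::sd(.data$visible_ctx),
                     n = dplyr::n(), .groups = "drop") |>
    (\(d) {
      missing <- setdiff(c("switch", "non_switch"), d$context)
      if (length(missing)) {
        d <- dplyr::bind_rows(d, tibble::tibble(
          context = missing, mean = NA_real_, sd = NA_real_, n = 0L))
      }
      dplyr::arrange(d, dplyr::desc(.data$context))
    })()
}

per_episode_metrics <- function(trace, env_cfgs) {
  fin <- attr(trace, "final_states")
  dec <- episode_decisions(trace)
  sr1 <- success_rate(fin[[1]], env_cfgs[[1]])
  sr2 <- success_rate(fin[[2]], env_cfgs[[2]])
  tibble::tibble(
    sr_overall = (sr1 + sr2) / 2,
    sr_task1 = sr1, sr_task2 = sr2,
    engagement_task1 = engagement_ratio(trace, 0L),
    n_switches = sum(dec$switch),
    n_decisions = nrow(dec)
  )
}

resolve_meta_policy <- function(agent) {
  if (is.function(agent)) return(agent)
  if (inherits(agent, "meta_agent_ckpt")) return(as_meta_policy(agent))
  if (is.character(agent) && length(agent) == 1L) {
    return(switch(agent,
      sef = switch_every_frame_policy,
      never_switch_task1 = constant_meta_policy(0L),
      never_switch_task2 = constant_meta_policy(1L),
      random = function(d, obs) sample(0:1, 1L),
      stop("unknown baseline agent: ", agent, call. = FALSE)))
  }
  stop("agent must be a function, a meta checkpoint, or a baseline name",
       call. = FALSE)
}

#' Evaluate meta-agents on one block
#'
#' Runs `n_episodes` multitask episodes per agent, reusing the same
#' per-episode world seeds for every agent so that cross-agent differences
#' are not driven by world sampling, and aggregates the behavioral metrics:
#' overall and per-task success rates, engagement ratio of task one, switch
#' counts, per-decision switching ratios and the visible-asteroid context
#' of switch vs. non-switch decisions.
#'
#' @param agents Named list of meta policies: functions, trained
#'   `meta_agent_ckpt`s, or baseline names (`"sef"`,
#'   `"never_switch_task1"`, `"never_switch_task2"`, `"random"`).
#' @param block_id Block identifier from [enumerate_blocks()].
#' @param sub_policies List of two sub-policies (default greedy oracle for
#'   both tasks).
#' @param n_episodes Episodes per agent (default 100).
#' @param seed Base seed from which the shared per-episode world seeds are
#'   drawn.
#' @param meta_cfg,soc_cfg Shared meta/SoC configuration.
#' @param compute_soc Compute SoC columns in the traces (required when any
#'   agent observes or is rewarded by SoC).
#' @param keep_traces Keep the raw episode traces in the result.
#' @param ... Further arguments to [env_config()] via
#'   [block_env_configs()].
#' @return An object of class `mt_evaluation`: list with `episodes`
#'   (per-episode tibble), `summary` (per-agent means and SDs),
#'   `switching_ratio`, `asteroids`, `block_id`, and optionally `traces`.
#' @export
evaluate <- function(agents, block_id, sub_policies = NULL,
                     n_episodes = 100L, seed = 1L,
                     meta_cfg = meta_config(), soc_cfg = soc_config(),
                     compute_soc = TRUE, keep_traces = FALSE, ...) {
  stopifnot(length(agents) >= 1, !is.null(names(agents)),
            all(nzchar(names(agents))))
  env_cfgs <- block_env_configs(block_id, ...)
  if (is.null(sub_policies)) sub_policies <- list(greedy_policy, greedy_policy)
  set.seed(seed)
  seed_pairs <- matrix(sample.int(1e6, 2L * n_episodes), ncol = 2L)
  episodes <- vector("list", length(agents))
  switching <- vector("list", length(agents))
  asteroids <- vector("list", length(agents))
  all_traces <- if (keep_traces) list() else NULL
  for (ai in seq_along(agents)) {
    nm <- names(agents)[ai]
    pol <- resolve_meta_policy(agents[[ai]])
    # a trained checkpoint is evaluated under its own observation/reward mode
    agent_meta_cfg <- if (inherits(agents[[ai]], "meta_agent_ckpt")) {
      agents[[ai]]$meta_config
    } else meta_cfg
    traces <- vector("list", n_episodes)
    rows <- vector("list", n_episodes)
    for (e in seq_len(n_episodes)) {
      tr <- run_multitask_episode(pol, sub_policies, env_cfgs,
                                  agent_meta_cfg,
                                  soc_cfg, seeds = seed_pairs[e, ],
                                  compute_soc = compute_soc)
      traces[[e]] <- tr
      rows[[e]] <- dplyr::mutate(per_episode_metrics(tr, env_cfgs),
                                 agent = nm, episode = e,
                                 seed_task1 = seed_pairs[e, 1],
                                 seed_task2 = seed_pairs[e, 2],
                                 .before = 1)
    }
    episodes[[ai]] <- dplyr::bind_rows(rows)
    switching[[ai]] <- dplyr::mutate(switching_ratio_per_timestep(traces),
                                     agent = nm, .before = 1)
    asteroids[[ai]] <- dplyr::mutate(asteroids_at_switch(traces),
                                     agent = nm, .before = 1)
    if (keep_traces) all_traces[[nm]] <- traces
  }
  episodes <- dplyr::bind_rows(episodes)
  summary <- episodes |>
    dplyr::group_by(.data$agent) |>
    dplyr::summarise(
      n_episodes = dplyr::n(),
      dplyr::across(c("sr_overall", "sr_task1", "sr_task2",
                      "engagement_task1", "n_switches"),
                    list(mean = mean, sd = stats::sd)),
      .groups = "drop")
  structure(list(block_id = block_id, episodes = episodes,
                 summary = summary,
                 switching_ratio = dplyr::bind_rows(switching),
                 asteroids = dplyr::bind_rows(asteroids),
                 traces = all_traces),
            class = "mt_evaluation")
}

#' @export
print.mt_evaluation <- function(x, ...) {
  cat("<mt_evaluation> block ", x$block_id, ", ",
      length(unique(x$episodes$agent)), " agent(s), ",
      max(x$episodes$episode), " episodes each\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Export an episode trace to CSV
#'
#' Writes the per-frame trace and, alongside it, a `-decisions.csv` with
#' the per-decision records and a `-meta.yaml` sidecar holding block and
#' seed metadata.
#'
#' @param trace An `episode_trace`.
#' @param path Output CSV path.
#' @param block_id Optional block identifier stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, block_id = NULL) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  dec_path <- sub("\\.csv$", "-decisions.csv", path)
  utils::write.csv(as.data.frame(episode_decisions(trace)), dec_path,
                   row.names = FALSE)
  meta <- list(block_id = block_id,
               seeds = as.list(attr(trace, "seeds")),
               episode_length = nrow(trace))
  yaml::write_yaml(meta, sub("\\.csv$", "-meta.yaml", path))
  invisible(path)
}
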