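#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sub-agent training checkpoint
#'
#' @param x A `sub_agent_ckpt`.
#' @param ... Unused.
#' @return The learning curve: one row per PPO update with the cumulative
#'   step count and mean rewards.
#' @export
tidy.sub_agent_ckpt <- function(x, ...) x$curve

#' @rdname tidy.sub_agent_ckpt
#' @export
tidy.meta_agent_ckpt <- function(x, ...) x$curve

#' One-line summary of a training checkpoint
#'
#' @param x A `sub_agent_ckpt` or `meta_agent_ckpt`.
#' @param ... Unused.
#' @return One-row tibble: steps consumed, mean training reward, seed.
#' @export
glance.sub_agent_ckpt <- function(x, ...) {
  tibble::tibble(total_steps = x$total_steps, mean_reward = x$mean_reward,
                 seed = x$seed)
}

#' @rdname glance.sub_agent_ckpt
#' @export
glance.meta_agent_ckpt <- function(x, ...) {
  tibble::tibble(total_steps = x$total_steps, mean_reward = x$mean_reward,
                 seed = x$seed, agent_label = x$meta_config$agent_label)
}

#' Tidy block-wise statistics
#'
#' @param x A `block_stats` object.
#' @param ... Unused.
#' @return The Holm-adjusted pairwise comparison table (empty when the
#'   groups were degenerate).
#' @export
tidy.block_stats <- function(x, ...) {
  if (x$degenerate || is.null(x$pairwise)) {
    return(tibble::tibble(group1 = character(), group2 = character(),
                          estimate = numeric(), statistic = numeric(),
                          p_value = numeric(), p_adj = numeric(),
                          significant = logical()))
  }
  x$pairwise
}

#' @rdname tidy.block_stats
#' @export
glance.block_stats <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          bartlett_statistic = NA_real_,
                          bartlett_p_value = NA_real_,
                          n_groups = length(x$groups), degenerate = TRUE))
  }
  tibble::tibble(
    statistic = x$anova$statistic, p_value = x$anova$p_value,
    bartlett_statistic = if (is.null(x$bartlett)) NA_real_ else
      x$bartlett$statistic,
    bartlett_p_value = if (is.null(x$bartlett)) NA_real_ else
      x$bartlett$p_value,
    n_groups = length(x$groups), degenerate = FALSE)
}

#' Tidy an evaluation result
#'
#' @param x An `mt_evaluation` from [evaluate()].
#' @param ... Unused.
#' @return The per-episode metrics tibble.
#' @export
tidy.mt_evaluation <- function(x, ...) x$episodes

#' @rdname tidy.mt_evaluation
#' @export
glance.mt_evaluation <- function(x, ...) x$summary
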