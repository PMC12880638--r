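#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the SoC time courses of a multitask episode
#'
#' Shows both tasks' SoC trajectories over the episode, shading the frames
#' during which each task was attended.
#'
#' @param object An `episode_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.episode_trace <- function(object, ...) {
  long <- object |>
    dplyr::select("step", "active_task", "soc_task0", "soc_task1") |>
    tidyr::pivot_longer(c("soc_task0", "soc_task1"),
                        names_to = "task", values_to = "soc") |>
    dplyr::mutate(task = ifelse(.data$task == "soc_task0",
                                "task one", "task two"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$soc,
                                     colour = .data$task)) +
    ggplot2::geom_step() +
    ggplot2::geom_rug(
      data = dplyr::filter(object, .data$active_task == 0L),
      ggplot2::aes(x = .data$step), inherit.aes = FALSE,
      sides = "b", alpha = 0.3, length = ggplot2::unit(0.02, "npc")) +
    ggplot2::labs(x = "step", y = "sense of control", colour = NULL,
                  title = "SoC over one multitask episode",
                  subtitle = "rug: frames with task one attended") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot per-decision switching ratios
#'
#' Switching ratio at each decision index, one line per agent, with the
#' asteroid-free phases shaded.
#'
#' @param object An `mt_evaluation` from [evaluate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mt_evaluation <- function(object, ...) {
  sw <- object$switching_ratio
  spans <- dplyr::filter(sw[!duplicated(sw$decision), ], .data$in_free_span)
  p <- ggplot2::ggplot(sw, ggplot2::aes(x = .data$decision, y = .data$ratio,
                                        colour = .data$agent))
  if (nrow(spans)) {
    p <- p + ggplot2::geom_vline(xintercept = spans$decision,
                                 colour = "pink", alpha = 0.5)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::labs(x = "decision index", y = "switching ratio",
                  colour = NULL,
                  title = paste0("Switching ratio per decision - ",
                                 object$block_id),
                  subtitle = "vertical bands: asteroid-free phases") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Success-rate distributions per agent
#'
#' Box plot of per-episode overall success rates by agent, with the mean
#' marked, for one evaluated block.
#'
#' @param ev An `mt_evaluation`.
#' @return A ggplot object.
#' @export
plot_block_sr <- function(ev) {
  ggplot2::ggplot(ev$episodes,
                  ggplot2::aes(x = .data$agent, y = .data$sr_overall)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 17,
                          size = 3, colour = "red") +
    ggplot2::labs(x = NULL, y = "success rate",
                  title = paste0("Success rates - ", ev$block_id),
                  subtitle = "triangle: mean") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
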