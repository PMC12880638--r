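#' Holm step-down adjustment
#'
#' Direct implementation of the Holm multiple-testing correction: order the
#' p-values increasingly, multiply the i-th smallest by (m - i + 1),
#' enforce monotonicity by running maxima, and cap at 1. Equivalent to
#' `stats::p.adjust(p, "holm")`.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  m <- length(p)
  ord <- order(p)
  scaled <- (m - seq_len(m) + 1L) * p[ord]
  adj <- pmin(cummax(scaled), 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

#' Block-wise comparison of agent success rates
#'
#' For one block's per-episode success-rate samples, runs a one-way ANOVA
#' across agents, Bartlett's test of homoscedasticity, and all pairwise
#' two-tailed Welch t-tests with Holm-adjusted p-values, flagging
#' significance at the chosen alpha. Groups that are all degenerate (zero
#' variance everywhere) are reported as such and the tests skipped.
#'
#' @param data Data frame with one row per episode.
#' @param value Column with the measured success rates (default
#'   `sr_overall`).
#' @param group Column identifying the agent (default `agent`).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `block_stats`; see [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
block_statistics <- function(data, value = "sr_overall", group = "agent",
                             alpha = 0.05) {
  y <- data[[value]]
  g <- factor(data[[group]])
  stopifnot(!is.null(y), !is.null(g), nlevels(g) >= 2)
  sizes <- table(g)
  if (any(sizes < 2)) stop("each group needs at least 2 samples")
  vars <- tapply(y, g, stats::var)
  degenerate <- all(vars == 0)
  if (degenerate) {
    return(structure(list(degenerate = TRUE, alpha = alpha,
                          groups = levels(g), anova = NULL, bartlett = NULL,
                          pairwise = NULL),
                     class = "block_stats"))
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  bart <- if (any(vars == 0)) NULL else stats::bartlett.test(y, g)
  pairs <- utils::combn(levels(g), 2L)
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ya <- y[g == a]; yb <- y[g == b]
    if (stats::var(ya) == 0 && stats::var(yb) == 0) {
      tibble::tibble(group1 = a, group2 = b, estimate = mean(ya) - mean(yb),
                     statistic = NA_real_, p_value = NA_real_)
    } else {
      tt <- stats::t.test(ya, yb, alternative = "two.sided")
      tibble::tibble(group1 = a, group2 = b,
                     estimate = unname(diff(rev(tt$estimate))),
                     statistic = unname(tt$statistic),
                     p_value = tt$p.value)
    }
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_adj <- NA_real_
  ok <- !is.na(pw$p_value)
  pw$p_adj[ok] <- holm_adjust(pw$p_value[ok])
  pw$significant <- !is.na(pw$p_adj) & pw$p_adj < alpha
  structure(list(
    degenerate = FALSE, alpha = alpha, groups = levels(g),
    anova = list(statistic = tab[["F value"]][1],
                 p_value = tab[["Pr(>F)"]][1],
                 df = unname(tab[["Df"]])),
    bartlett = if (is.null(bart)) NULL else
      list(statistic = unname(bart$statistic), p_value = bart$p.value),
    pairwise = pw
  ), class = "block_stats")
}

#' @export
print.block_stats <- function(x, ...) {
  if (x$degenerate) {
    cat("<block_stats> all groups degenerate (zero variance); tests skipped\n")
    return(invisible(x))
  }
  cat("<block_stats> one-way ANOVA: F = ", format(x$anova$statistic, digits = 4),
      ", p = ", format(x$anova$p_value, digits = 3), "\n", sep = "")
  if (!is.null(x$bartlett)) {
    cat("Bartlett: K2 = ", format(x$bartlett$statistic, digits = 4),
        ", p = ", format(x$bartlett$p_value, digits = 3), "\n", sep = "")
  }
  cat("Holm-adjusted pairwise t-tests (alpha = ", x$alpha, "):\n", sep = "")
  print(x$pairwise)
  invisible(x)
}
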