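#' Peak map of a cohort or profile
#'
#' The classic CE-MS compiled view: log10 mass against migration time, point
#' size encoding log10 signal amplitude.
#'
#' @param peaks Long peak or cluster tibble (`mass`, `time`, `amplitude`).
#' @param colour_by Optional column name used for the point colour (e.g.
#'   `"sample_id"`).
#' @return A ggplot object.
#' @export
plot_peak_map <- function(peaks, colour_by = NULL) {
  p <- ggplot2::ggplot(peaks, ggplot2::aes(x = .data$time,
                                           y = log10(.data$mass)))
  if (!is.null(colour_by)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(size = log10(.data$amplitude),
                   colour = .data[[colour_by]]), alpha = 0.4)
  } else {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(size = log10(.data$amplitude)), alpha = 0.4)
  }
  p + ggplot2::scale_size_continuous(range = c(0.1, 2)) +
    ggplot2::labs(x = "migration time [min]", y = "log10 mass [Da]",
                  size = "log10 amplitude") +
    ggplot2::theme_minimal()
}

#' @describeIn discover_markers Volcano-style view of the marker statistics:
#'   signed regulation against -log10 adjusted p, candidates highlighted.
#' @param object A `marker_stats` tibble.
#' @param ... Unused.
#' @export
autoplot.marker_stats <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$regulation,
                               y = -log10(.data$p_bh),
                               colour = .data$candidate)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "regulation (signed fold)",
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "candidate") +
    ggplot2::theme_minimal()
}

#' @describeIn score_samples Strip plot of panel scores with the diagnostic
#'   cut-off line (when set).
#' @param object A `panel_scores` tibble.
#' @param groups Optional metadata tibble (`sample_id`, `group`) for the
#'   x-axis grouping.
#' @param ... Unused.
#' @export
autoplot.panel_scores <- function(object, groups = NULL, ...) {
  dat <- tibble::as_tibble(object)
  dat$group <- if (is.null(groups)) "all" else
    groups$group[match(dat$sample_id, groups$sample_id)]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$group,
                                         y = .data$score)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = NULL,
                  y = sprintf("%s score [a.u.]",
                              attr(object, "panel_id") %||% "panel")) +
    ggplot2::theme_minimal()
  cutoff <- attr(object, "cutoff")
  if (!is.null(cutoff) && !is.na(cutoff)) {
    p <- p + ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed")
  }
  p
}

#' @describeIn stability_analysis Replicate scores against time with the
#'   fitted least-squares trend.
#' @param object A `stability_report` is summary-only; supply the raw
#'   `times` and `scores` instead.
#' @export
plot_stability <- function(times, scores) {
  dat <- tibble::tibble(time = times, score = scores)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = "time [h]", y = "score [a.u.]") +
    ggplot2::theme_minimal()
}
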