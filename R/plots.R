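#' Staircase / posterior-track plot of a session
#'
#' For a SIAM session: the tracked concentration over trials with the
#' outcome of every trial; reversals are circled. For a QUEST session: the
#' presented concentrations and the evolving posterior mean with its 5-95%
#' posterior interval.
#'
#' @param object A `taste_session`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot siam_session
#' @export
autoplot.siam_session <- function(object, ...) {
  trials <- object$trials
  revs <- detect_reversals(object)
  p <- ggplot2::ggplot(trials,
                       ggplot2::aes(x = .data$trial, y = .data$level_log10)) +
    ggplot2::geom_step(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$kind,
                                     colour = .data$outcome), size = 2) +
    ggplot2::labs(x = "Trial", y = "Tracked level (log10 mM)",
                  title = "SIAM staircase") +
    ggplot2::theme_minimal()
  if (nrow(revs) > 0) {
    p <- p + ggplot2::geom_point(data = revs,
                                 ggplot2::aes(x = .data$trial,
                                              y = .data$log10_mM),
                                 shape = 1, size = 4, inherit.aes = FALSE)
  }
  if (!is.na(object$estimate)) {
    p <- p + ggplot2::geom_hline(yintercept = object$estimate,
                                 linetype = "dashed")
  }
  p
}

#' @rdname autoplot.siam_session
#' @method autoplot quest_session
#' @export
autoplot.quest_session <- function(object, ...) {
  trials <- object$trials
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$post_mean)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$log10_mM,
                                     colour = .data$response), size = 2) +
    ggplot2::labs(x = "Trial", y = "log10 mM",
                  title = "QUEST session",
                  subtitle = "points: presented levels; line: posterior mean; band: 5-95% interval") +
    ggplot2::theme_minimal()
}

#' Histogram of threshold estimates over dilution steps
#'
#' @param histogram Output of [histogram_by_step()].
#' @return A ggplot object.
#' @export
plot_step_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = factor(.data$sample), y = .data$count,
                               fill = .data$extreme)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "steelblue",
                                          `TRUE` = "firebrick"),
                               guide = "none") +
    ggplot2::labs(x = "Dilution step (1 = strongest)",
                  y = "Threshold count") +
    ggplot2::theme_minimal()
}

#' Test-retest scatter plot per taste quality and method
#'
#' @param pairs Pair table from [threshold_pairs()].
#' @return A ggplot object with one panel per quality x method cell and the
#'   identity line.
#' @export
plot_test_retest <- function(pairs) {
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$test, y = .data$retest)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_grid(method ~ quality) +
    ggplot2::labs(x = "Test threshold (log10 mM)",
                  y = "Retest threshold (log10 mM)") +
    ggplot2::theme_minimal()
}
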