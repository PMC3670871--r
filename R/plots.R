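# Optional figures (ggplot2 in Suggests); every quantity plotted is also
# written as TSV/JSON, so headless runs need no graphics stack.

#' Plot the rank-stability profile of the top features
#'
#' Mean rank with the empirical 95% rank interval for the top features (by
#' mean p-value) at one subsample size; wider ribbons mean less reproducible
#' rank order.
#'
#' @param profile a [RankProfile-class].
#' @param top how many top features to show (default 100).
#' @return A ggplot object.
#' @export
plotRankProfile <- function(profile, top = 100L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plotRankProfile requires ggplot2")
  st <- rankTable(profile)
  st <- st[order(st$mean_p, st$mean_rank), , drop = FALSE]
  st <- utils::head(st, top)
  st$position <- seq_len(nrow(st))
  ggplot2::ggplot(st, ggplot2::aes(x = .data$position, y = .data$mean_rank)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rank_lo,
                                      ymax = .data$rank_hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "feature (ordered by mean p-value)",
                  y = "rank (mean and 95% interval)",
                  title = sprintf("Rank stability at n = %s, %d repeats",
                                  ifelse(is.na(profile@n), "?", profile@n),
                                  profile@repeats)) +
    ggplot2::theme_minimal()
}

#' Plot a learning curve
#'
#' Box plot of per-repeat classifier accuracies by training-set size.
#'
#' @param lc a [LearningCurve-class].
#' @return A ggplot object.
#' @export
plotLearningCurve <- function(lc) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stopf("plotLearningCurve requires ggplot2")
  tab <- curveTable(lc)
  ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$n),
                                    y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "training-set size n", y = "accuracy",
                  title = sprintf("Sex-prediction accuracy (%s)", lc@mode)) +
    ggplot2::theme_minimal()
}
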