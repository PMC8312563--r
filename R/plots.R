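# ggplot2 displays of analysis results.

#' Threshold-sweep plot of global parameters
#'
#' Group means with standard-deviation error bars for each global parameter
#' as a function of the fiber-number threshold — the standard robustness
#' display for thresholded connectome analyses.
#'
#' @param object A `wmnet_analysis` object.
#' @param metrics Character vector of sweep columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wmnet_analysis
#' @export
autoplot.wmnet_analysis <- function(object,
                                    metrics = c("gamma", "lambda", "sigma",
                                                "cp", "lp", "loce", "ge"),
                                    ...) {
  metrics <- intersect(metrics, names(object$sweep))
  dat <- dplyr::left_join(object$sweep,
                          object$cohort[, c("subject_id", "group")],
                          by = "subject_id")
  long <- tidyr::pivot_longer(dat, cols = dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  summ <- dplyr::summarise(
    dplyr::group_by(long, .data$group, .data$fn, .data$metric),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$fn), y = .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fiber-number threshold", y = "group mean ± sd") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Hub-score bar plot
#'
#' Nodes sorted by hubness score, hubs highlighted.
#'
#' @param hub_table A table from [hubness_scores()].
#' @return A ggplot object.
#' @export
plot_hub_scores <- function(hub_table) {
  dat <- dplyr::arrange(hub_table, dplyr::desc(.data$score), .data$label)
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$score,
                                    fill = .data$is_hub)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#E8B800",
                                          `FALSE` = "grey70"),
                               name = "hub (score ≥ 2)") +
    ggplot2::labs(x = NULL, y = "hubness score (0-4)") +
    ggplot2::theme_minimal(base_size = 8)
}
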