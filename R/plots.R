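#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: the MI weight
#' distribution of a network, removals per DPI order of a pruning run, and
#' per-order removal / precision panels of a saturation experiment.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot object.
#' @name haracne-autoplot
NULL

#' @rdname haracne-autoplot
#' @export
autoplot.mi_network <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$mi)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::labs(
      x = "mutual information (nats)", y = "edges",
      title = sprintf(
        "MI network: %d edges, %d nodes",
        nrow(object), length(network_nodes(object))
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname haracne-autoplot
#' @export
autoplot.dpi_prune <- function(object, ...) {
  po <- per_order_summary(object)
  ggplot2::ggplot(po, ggplot2::aes(x = factor(.data$order), y = .data$removed)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(
      x = "DPI order", y = "edges removed",
      title = "Indirect interactions removed per DPI order"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname haracne-autoplot
#' @export
autoplot.saturation_experiment <- function(object, ...) {
  df <- as_tibble(object) |>
    select("order", "removed", "precision") |>
    tidyr::pivot_longer(c("removed", "precision"),
      names_to = "metric", values_to = "value"
    ) |>
    filter(!(.data$metric == "removed" & .data$order == 0))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$order), y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "DPI order (0 = relevance network)", y = NULL,
      title = "Higher-order DPI saturation across seeds"
    ) +
    ggplot2::theme_minimal()
}
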