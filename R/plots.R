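# ggplot2 displays: the three stacked per-column tracks (Gaps / AAC / CAP)
# and the census heatmap.

#' Plot per-column conservation tracks
#'
#' Three stacked panels over the alignment columns -- gap fraction, amino
#' acid conservation (AAC) and conservation of amyloidogenic properties
#' (CAP) -- with one line per sampling replicate when a `replicate` column
#' is present.
#'
#' @param object Metrics table from [column_metrics()] (optionally with a
#'   `replicate` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amyloscan_metrics <- function(object, ...) {
  long <- object |>
    select(dplyr::any_of("replicate"), "column", "gaps_fraction",
           "aac", "cap") |>
    tidyr::pivot_longer(c("gaps_fraction", "aac", "cap"),
                        names_to = "metric", values_to = "value") |>
    mutate(metric = factor(.data$metric,
                           levels = c("gaps_fraction", "aac", "cap"),
                           labels = c("Gaps", "AAC", "CAP")))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$value))
  if ("replicate" %in% names(object)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$replicate),
                                alpha = 0.4, linewidth = 0.3)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.4)
  }
  p +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$metric)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.amyloscan_metrics
#' @param metrics Metrics table.
#' @export
plot_column_metrics <- function(metrics, ...) {
  autoplot.amyloscan_metrics(metrics, ...)
}

#' Plot the per-taxon amyloid census as a heatmap
#'
#' One tile per (gene, taxon) coloured by the proportion of potential
#' amyloids, annotated with the number of analysed sequences.
#'
#' @param object Census table from [census()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amyloscan_census <- function(object, ...) {
  level <- attr(object, "group_level") %||%
    setdiff(names(object), c("gene", "n_proteins", "n_amyloid",
                             "proportion"))[1]
  d <- as_tibble(object)
  if (!"gene" %in% names(d)) d$gene <- "family"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data[[level]],
                                  fill = .data$proportion)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_proteins), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1),
                                 name = "proportion\namyloidogenic") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.amyloscan_census
#' @param census_table Census table.
#' @export
plot_census <- function(census_table, ...) {
  autoplot.amyloscan_census(census_table, ...)
}
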