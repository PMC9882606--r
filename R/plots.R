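# ggplot2 front-ends for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a selectivity profile score distribution
#'
#' Histogram of best combo scores across the library, with labelled entries
#' of interest marked by vertical lines.
#'
#' @param object a `selectivity_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.selectivity_profile <- function(object, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$S_combo)) +
    ggplot2::geom_histogram(
      breaks = c(object$histogram$lower[1], object$histogram$upper),
      fill = "grey70", colour = "grey30", linewidth = 0.2
    ) +
    ggplot2::labs(
      x = "best combo score vs library entry", y = "pharmacophores",
      title = object$compound
    ) +
    ggplot2::theme_minimal()
  marked <- dplyr::filter(sc, !is.na(.data$label))
  if (nrow(marked) > 0) {
    p <- p +
      ggplot2::geom_vline(
        data = marked,
        ggplot2::aes(xintercept = .data$S_combo, colour = .data$label),
        linewidth = 0.7
      ) +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Plot the 2-D pharmacophore map
#'
#' @param object a `phore_map` from [mds_embed()].
#' @param highlight character vector of entry ids to emphasise.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phore_map <- function(object, highlight = character(), ...) {
  co <- dplyr::mutate(object$coords,
    highlighted = .data$id %in% highlight
  )
  ggplot2::ggplot(co, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$highlighted), size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey50", `TRUE` = "magenta"), guide = "none"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "MDS 1", y = "MDS 2",
      subtitle = sprintf("normalized stress %.3g", object$stress_norm)
    ) +
    ggplot2::theme_minimal()
}
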