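#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a directed network
#'
#' Draws the network with a force-directed layout; targets, inputs and
#' preferred sources can be highlighted.
#'
#' @param object a [network()] object.
#' @param highlight optional named list of character vectors (e.g.
#'   `list(target = ..., input = ...)`); listed nodes are coloured by
#'   group.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ctrl_network
#' @export
autoplot.ctrl_network <- function(object, highlight = NULL, ...) {
  xy <- igraph::layout_with_fr(as_igraph(object))
  nodes <- tibble::tibble(
    node = object$nodes, x = xy[, 1], y = xy[, 2], group = "node"
  )
  for (g in names(highlight)) {
    nodes$group[nodes$node %in% highlight[[g]]] <- g
  }
  ed <- dplyr::mutate(
    as_tibble(object),
    x = nodes$x[match(.data$from, nodes$node)],
    y = nodes$y[match(.data$from, nodes$node)],
    xend = nodes$x[match(.data$to, nodes$node)],
    yend = nodes$y[match(.data$to, nodes$node)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      arrow = grid::arrow(length = grid::unit(2, "mm")),
      colour = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$group), size = 3
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = -1, size = 3
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}

#' Plot the objective profile of a solution set
#'
#' One bar per ranked solution: total inputs, with the preferred
#' (drug-targetable) inputs shown as a darker segment.
#'
#' @param object a `ctrl_solution_set` from [greedy_control()] or
#'   [ga_control()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ctrl_solution_set
#' @export
autoplot.ctrl_solution_set <- function(object, ...) {
  gl <- glance(object)
  long <- tidyr::pivot_longer(
    dplyr::transmute(
      gl,
      solution = factor(.data$solution),
      preferred = .data$n_preferred,
      other = .data$n_inputs - .data$n_preferred
    ),
    cols = c("preferred", "other"),
    names_to = "kind", values_to = "count"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$solution, y = .data$count, fill = .data$kind)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "solution (ranked by objective)", y = "control inputs",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}
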