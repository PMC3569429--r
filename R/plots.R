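# ggplot2 views of the main result types

#' Plot a digraph
#'
#' Force-directed layout (seeded Fruchterman–Reingold via igraph) with arcs
#' drawn as arrows. Intended for the small networks this package targets.
#'
#' @param object A `digraph`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot digraph
#' @export
autoplot.digraph <- function(object, seed = 1L, ...) {
  ig <- as_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(ig))
  nodes <- tibble(node = graph_nodes(object), x = xy[, 1L], y = xy[, 2L])
  arcs <- tibble(
    x = nodes$x[match(object$from, nodes$node)],
    y = nodes$y[match(object$from, nodes$node)],
    xend = nodes$x[match(object$to, nodes$node)],
    yend = nodes$y[match(object$to, nodes$node)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = arcs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      arrow = grid::arrow(length = grid::unit(2, "mm")), colour = "grey40"
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 3) +
    ggplot2::geom_text(
      data = nodes, ggplot2::aes(.data$x, .data$y, label = .data$node),
      vjust = -1, size = 3
    ) +
    ggplot2::theme_void()
}

#' Plot a potential assignment as a layered hierarchy
#'
#' Nodes are placed at height equal to their potential (the local hierarchy
#' level), spread horizontally within each level; every arc then points
#' downward by exactly one level. Errors for non-definable graphs.
#'
#' @param object A `potential_fit` with `definable = TRUE`, together with the
#'   digraph it was fitted on (`graph`).
#' @param graph The `digraph` the potentials were fitted on.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot potential_fit
#' @export
autoplot.potential_fit <- function(object, graph, ...) {
  if (!object$definable) {
    abort("Graph is not potential-definable; there is no layered drawing. Inspect `$witness`.")
  }
  pot <- object$potentials
  nodes <- tibble(node = names(pot), potential = unname(pot)) |>
    group_by(.data$potential) |>
    mutate(x = seq_along(.data$node) - (dplyr::n() + 1) / 2) |>
    ungroup()
  arcs <- tibble(
    x = nodes$x[match(graph$from, nodes$node)],
    y = nodes$potential[match(graph$from, nodes$node)],
    xend = nodes$x[match(graph$to, nodes$node)],
    yend = nodes$potential[match(graph$to, nodes$node)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = arcs,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      arrow = grid::arrow(length = grid::unit(2, "mm")), colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = nodes, ggplot2::aes(.data$x, .data$potential),
      size = 4, colour = "steelblue"
    ) +
    ggplot2::geom_text(
      data = nodes, ggplot2::aes(.data$x, .data$potential, label = .data$node),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_y_continuous(breaks = unique(nodes$potential)) +
    ggplot2::labs(y = "potential level", x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot experiment results
#'
#' Mean AUC per predictor with one-standard-deviation error bars and the
#' 0.5 random-guess baseline.
#'
#' @param object A `link_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot link_experiment
#' @export
autoplot.link_experiment <- function(object, ...) {
  df <- as_tibble(object)
  df$predictor <- factor(df$predictor, levels = df$predictor)
  ggplot2::ggplot(df, ggplot2::aes(.data$predictor, .data$mean_auc)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_auc - .data$sd_auc,
        ymax = .data$mean_auc + .data$sd_auc
      ),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_point(size = 2.5, colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "AUC (mean ± sd over partitions)") +
    ggplot2::theme_minimal()
}
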