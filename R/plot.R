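#' Plot species networks
#'
#' `autoplot()` methods draw the package's network objects with ggplot2.
#' 3-way networks are drawn via their edge-node expansion (small square
#' edge-nodes linked to their three member species); bipartite enrichment
#' networks show species and shared-enriched family nodes. Layout is
#' Fruchterman-Reingold from igraph; pass `seed` for a reproducible
#' arrangement.
#'
#' @param object a network object.
#' @param genus_of optional named character vector (species -> genus)
#'   used to colour species nodes.
#' @param seed layout seed.
#' @param ... unused.
#' @return A ggplot object.
#' @name network_plots
NULL

layout_tbl <- function(g, seed) {
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  tibble::tibble(node = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}

plot_links <- function(nodes, links, colour_by_genus) {
  seg <- dplyr::left_join(links, nodes[c("node", "x", "y")],
                          by = c(from = "node"))
  seg <- dplyr::left_join(seg, nodes[c("node", "x", "y")],
                          by = c(to = "node"), suffix = c("", "_to"))
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_to, yend = .data$y_to,
                   linewidth = .data$weight),
      colour = "grey60", show.legend = FALSE) +
    ggplot2::scale_linewidth(range = c(0.2, 1)) +
    ggplot2::theme_void()
  sp <- nodes[nodes$kind == "species", , drop = FALSE]
  aux <- nodes[nodes$kind != "species", , drop = FALSE]
  if (nrow(aux) > 0) {
    p <- p + ggplot2::geom_point(
      data = aux, ggplot2::aes(x = .data$x, y = .data$y),
      shape = 15, size = 1.5, colour = "white") +
      ggplot2::geom_point(
        data = aux, ggplot2::aes(x = .data$x, y = .data$y),
        shape = 0, size = 1.5, colour = "grey40")
  }
  if (colour_by_genus) {
    p <- p + ggplot2::geom_point(
      data = sp, ggplot2::aes(x = .data$x, y = .data$y,
                              colour = .data$genus), size = 3)
  } else {
    p <- p + ggplot2::geom_point(
      data = sp, ggplot2::aes(x = .data$x, y = .data$y),
      colour = "grey35", size = 3)
  }
  p + ggplot2::geom_text(
    data = sp, ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
    size = 2.4, vjust = -1.1)
}

expanded_to_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$links[c("from", "to", "weight")], directed = FALSE,
    vertices = as.data.frame(graph$nodes["node"]))
}

#' @rdname network_plots
#' @exportS3Method ggplot2::autoplot
autoplot.tw_network2 <- function(object, genus_of = NULL, seed = 1, ...) {
  autoplot.tw_network3(object, genus_of = genus_of, seed = seed, ...)
}

#' @rdname network_plots
#' @exportS3Method ggplot2::autoplot
autoplot.tw_network3 <- function(object, genus_of = NULL, seed = 1, ...) {
  graph <- expand_for_viewer(object, genus_of = genus_of)
  g <- expanded_to_igraph(graph)
  nodes <- dplyr::left_join(layout_tbl(g, seed), graph$nodes, by = "node")
  plot_links(nodes, graph$links, !is.null(genus_of))
}

#' @rdname network_plots
#' @exportS3Method ggplot2::autoplot
autoplot.tw_network_mixed <- autoplot.tw_network3

#' @rdname network_plots
#' @exportS3Method ggplot2::autoplot
autoplot.tw_bipartite <- function(object, genus_of = NULL, seed = 1, ...) {
  links <- tibble::tibble(from = object$edges$family,
                          to = object$edges$species,
                          weight = 1)
  nodes <- object$nodes
  nodes$genus <- if (is.null(genus_of)) NA_character_ else
    unname(genus_of[nodes$node])
  nodes$kind <- ifelse(nodes$kind == "family", "edge-node", nodes$kind)
  g <- igraph::graph_from_data_frame(links, directed = FALSE,
                                     vertices = as.data.frame(nodes["node"]))
  nodes <- dplyr::left_join(layout_tbl(g, seed), nodes, by = "node")
  plot_links(nodes, links, !is.null(genus_of))
}
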