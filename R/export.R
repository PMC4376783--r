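#' Expand a 3-way network for standard graph viewers
#'
#' Graph viewers such as Cytoscape handle only pairwise edges, so each
#' 3-way hyperedge \eqn{\{u, v, w\}} is represented by an auxiliary
#' "edge-node" linked to its three members and carrying the hyperedge
#' weight. Pairwise edges of a mixed network pass through unchanged. The
#' expansion is invertible: edge-nodes are tagged by kind and named
#' deterministically (`"e:"` + the three sorted species labels joined by
#' `"|"`), and [collapse_expanded()] recovers the original network.
#'
#' @param network a `tw_network3`, mixed network, or `tw_network2`.
#' @param genus_of optional named character vector (species -> genus) for
#'   the node attribute table; unmapped nodes get `NA`.
#' @return An object of class `tw_expanded`: a list with tibbles
#'   `nodes` (`node`, `kind`, `genus`, `weight`) and
#'   `links` (`from`, `to`, `interaction`, `weight`), where interaction
#'   `"tw"` marks edge-node links and `"pw"` plain pairwise edges.
#' @examples
#' net <- new_network3(
#'   tibble::tibble(species_a = c("v1", "v3"), species_b = c("v2", "v4"),
#'                  species_c = c("v3", "v5"), weight = c(0.8, 0.9)),
#'   nodes = paste0("v", 1:5))
#' expand_for_viewer(net)
#' @export
expand_for_viewer <- function(network, genus_of = NULL) {
  tb <- tibble::as_tibble(network)
  if (!"species_c" %in% names(tb)) tb$species_c <- NA_character_
  species <- network_nodes(network)
  is3 <- !is.na(tb$species_c)
  tri <- tb[is3, , drop = FALSE]
  pw <- tb[!is3, , drop = FALSE]
  enode <- if (nrow(tri) > 0) {
    paste0("e:", apply(tri[c("species_a", "species_b", "species_c")], 1,
                       function(r) paste(sort(r), collapse = "|")))
  } else character(0)
  links <- dplyr::bind_rows(
    tibble::tibble(from = pw$species_a, to = pw$species_b,
                   interaction = "pw", weight = pw$weight),
    tibble::tibble(
      from = rep(enode, 3),
      to = c(tri$species_a, tri$species_b, tri$species_c),
      interaction = "tw",
      weight = rep(tri$weight, 3)
    )
  )
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = species, kind = "species",
                   genus = if (is.null(genus_of)) NA_character_ else
                     unname(genus_of[species]),
                   weight = NA_real_),
    tibble::tibble(node = enode, kind = "edge-node", genus = NA_character_,
                   weight = tri$weight)
  )
  structure(list(nodes = nodes, links = links), class = "tw_expanded")
}

#' @rdname expand_for_viewer
#' @param graph a `tw_expanded` object.
#' @return [collapse_expanded()] returns the original network: a
#'   `tw_network3` if the expansion held only hyperedges, otherwise a
#'   mixed network.
#' @export
collapse_expanded <- function(graph) {
  stopifnot(inherits(graph, "tw_expanded"))
  species <- graph$nodes$node[graph$nodes$kind == "species"]
  en <- graph$links[graph$links$interaction == "tw", , drop = FALSE]
  tri <- if (nrow(en) > 0) {
    purrr::map_dfr(split(en, en$from), function(d) {
      mem <- sort(d$to)
      tibble::tibble(species_a = mem[1], species_b = mem[2],
                     species_c = mem[3], weight = d$weight[1])
    })
  } else {
    tibble::tibble(species_a = character(), species_b = character(),
                   species_c = character(), weight = numeric())
  }
  pw <- graph$links[graph$links$interaction == "pw", , drop = FALSE]
  if (nrow(pw) == 0) {
    net3 <- new_network3(dplyr::arrange(tri, .data$species_a, .data$species_b,
                                        .data$species_c),
                         nodes = species)
    return(net3)
  }
  union_networks(
    new_network2(tibble::tibble(species_a = pw$from, species_b = pw$to,
                                weight = pw$weight), nodes = species),
    new_network3(tri, nodes = species)
  )
}

#' @export
print.tw_expanded <- function(x, ...) {
  cat(sprintf("<expanded graph> %d species, %d edge-nodes, %d links\n",
              sum(x$nodes$kind == "species"),
              sum(x$nodes$kind == "edge-node"), nrow(x$links)))
  invisible(x)
}

check_label_safety <- function(labels) {
  bad <- grepl("[\t\n]", labels)
  if (any(bad)) {
    abort(sprintf("labels may not contain tabs or newlines: %s",
                  paste(utils::head(labels[bad], 3), collapse = ", ")))
  }
}

#' Write graphs for external viewers
#'
#' Writes an expanded graph (or a plain 2-way network) as Cytoscape SIF,
#' GraphML, or an edge-list TSV; a node-attribute TSV
#' (`node`, `kind`, `genus`, `weight`) is written alongside as
#' `<path>.nodes.tsv`. SIF uses interaction type `"tw"` for edge-node
#' links and `"pw"` for pairwise edges. GraphML (written and read back
#' via igraph) carries the node kind, genus and weight attributes.
#'
#' @param graph a `tw_expanded` object or `tw_network2`.
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("sif", "graphml",
                                                     "edgelist")) {
  if (length(format) == 1 && !format %in% c("sif", "graphml", "edgelist")) {
    abort(sprintf("unknown graph format '%s'.", format))
  }
  format <- match.arg(format)
  if (inherits(graph, "tw_network2")) {
    graph <- expand_for_viewer(graph)
  }
  stopifnot(inherits(graph, "tw_expanded"))
  check_label_safety(graph$nodes$node)
  nodes <- graph$nodes
  links <- graph$links
  if (format == "sif") {
    con <- file(path, open = "w", encoding = "UTF-8")
    writeLines(paste(links$from, links$interaction, links$to, sep = "\t"),
               con)
    close(con)
  } else if (format == "edgelist") {
    con <- file(path, open = "w", encoding = "UTF-8")
    writeLines(paste(links$from, links$to, links$interaction,
                     sprintf("%.6f", links$weight), sep = "\t"), con)
    close(con)
  } else {
    g <- igraph::graph_from_data_frame(
      links[c("from", "to", "interaction", "weight")],
      directed = FALSE, vertices = as.data.frame(nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  attr_path <- paste0(path, ".nodes.tsv")
  con <- file(attr_path, open = "w", encoding = "UTF-8")
  writeLines(c(
    "node\tkind\tgenus\tweight",
    paste(nodes$node, nodes$kind,
          ifelse(is.na(nodes$genus), "", nodes$genus),
          ifelse(is.na(nodes$weight), "", sprintf("%.6f", nodes$weight)),
          sep = "\t")
  ), con)
  close(con)
  invisible(path)
}

#' Genus colour table for viewers
#'
#' Assigns one colour per genus for node colouring in external viewers;
#' species without a genus (or genera beyond the palette) default to
#' grey. Emitted as a table rather than baked into graph files.
#'
#' @param genus_of named character vector, species -> genus.
#' @param default colour for unmapped species.
#' @return A tibble `species`, `genus`, `color`.
#' @export
genus_color_table <- function(genus_of, default = "grey") {
  genera <- sort(unique(unname(genus_of)))
  pal <- grDevices::hcl.colors(max(length(genera), 2L), palette = "Dark 3")
  cols <- setNames(pal[seq_along(genera)], genera)
  tibble::tibble(
    species = names(genus_of),
    genus = unname(genus_of),
    color = unname(ifelse(is.na(genus_of), default, cols[genus_of]))
  )
}
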