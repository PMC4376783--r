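#' Prune reports
#'
#' Every pruning operation attaches a small report (strategy, parameters,
#' edge counts before and after) to its result; `prune_report()` retrieves
#' it as a one-row tibble.
#'
#' @param network a pruned network.
#' @return A tibble with columns `strategy`, `parameters`,
#'   `edges_before`, `edges_after`, or `NULL` if the network was never
#'   pruned.
#' @export
prune_report <- function(network) {
  attr(network, "prune_report")
}

set_report <- function(network, strategy, parameters, before) {
  attr(network, "prune_report") <- tibble::tibble(
    strategy = strategy, parameters = parameters,
    edges_before = before, edges_after = nrow(network)
  )
  network
}

# key used for deterministic tie-breaks and duplicate detection:
# sorted member labels joined by "|"
edge_key <- function(edges) {
  cols <- intersect(c("species_a", "species_b", "species_c"), names(edges))
  mem <- as.matrix(edges[cols])
  apply(mem, 1, function(r) paste(sort(stats::na.omit(r)), collapse = "|"))
}

#' Threshold pruning
#'
#' Removes edges whose weight falls below a threshold; edges with
#' `weight >= t` survive, so an edge at exactly 0.75 survives `t = 0.75`
#' but not the default `t = 0.76`. For 3-way Sorensen and Czekanowski
#' networks any threshold above 0.75 guarantees every surviving triplet
#' has a non-empty three-way intersection (see [similarity_indices]),
#' which is why 0.76 is the default. The node set is unchanged: species
#' that lose all their edges stay in the network as isolated nodes.
#'
#' @param network a `tw_network2` or `tw_network3`.
#' @param t threshold in `[0, 1]`; default 0.76.
#' @return The same kind of network, with a [prune_report()] attached.
#' @examples
#' m <- generate_sf(synthetic_config(seed = 1))
#' build_network3(m) |> prune_threshold(0.76)
#' @export
prune_threshold <- function(network, t = 0.76) {
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 1) {
    abort("`t` must be a single value in [0, 1].")
  }
  before <- nrow(network)
  out <- keep_edges(network, network$weight >= t)
  set_report(out, "threshold", sprintf("t=%g", t), before)
}

#' Best-x-edge pruning
#'
#' For each node, ranks its incident edges by weight (highest first, ties
#' broken by the lexicographic order of the sorted member labels) and
#' keeps the top `x`; the pruned network is the union over nodes, so an
#' edge kept for any of its members is kept. Nodes with fewer than `x`
#' incident edges contribute all of them. The networks reported here use
#' `x = 2` (each species keeps its best and second-best edge).
#'
#' @inheritParams prune_threshold
#' @param x number of edges to keep per node (>= 1).
#' @return The same kind of network, with a [prune_report()] attached.
#' @export
prune_best_edges <- function(network, x = 2) {
  if (!is.numeric(x) || length(x) != 1 || x < 1 || x != round(x)) {
    abort("`x` must be a positive integer.")
  }
  cols <- intersect(c("species_a", "species_b", "species_c"), names(network))
  ord <- order(-network$weight, edge_key(network))  # weight desc, then key
  rank <- integer(nrow(network))
  rank[ord] <- seq_along(ord)
  kept <- logical(nrow(network))
  member <- unlist(network[cols], use.names = FALSE)
  edge_of <- rep(seq_len(nrow(network)), times = length(cols))
  for (rows in split(edge_of, member)) {
    top <- rows[order(rank[rows])][seq_len(min(x, length(rows)))]
    kept[top] <- TRUE
  }
  before <- nrow(network)
  out <- keep_edges(network, kept)
  set_report(out, "best_x", sprintf("x=%d", as.integer(x)), before)
}

#' Maximum spanning tree
#'
#' Extracts the backbone of a similarity network: edge weights are
#' inverted to distances (`w' = 1 - w`) and a minimum spanning tree of
#' the distance network is computed, which is the spanning tree of
#' maximum total similarity. Kruskal's algorithm is used with ties broken
#' by the lexicographic order of the sorted member labels, so output is
#' deterministic. A disconnected network yields a maximum spanning
#' forest (one tree per connected component) rather than an error.
#'
#' @param network a `tw_network2`.
#' @return A `tw_network2` holding the tree/forest edges, with a
#'   [prune_report()] attached.
#' @export
max_spanning_tree <- function(network) {
  stopifnot(inherits(network, "tw_network2") ||
              all(c("species_a", "species_b", "weight") %in% names(network)))
  nodes <- network_nodes(network)
  parent <- setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(1 - network$weight, edge_key(network))  # distance asc
  kept <- logical(nrow(network))
  for (e in ord) {
    ra <- find(match(network$species_a[e], nodes))
    rb <- find(match(network$species_b[e], nodes))
    if (ra != rb) {
      parent[ra] <- rb
      kept[e] <- TRUE
    }
  }
  before <- nrow(network)
  out <- keep_edges(network, kept)
  set_report(out, "mst", "w'=1-w", before)
}

keep_edges <- function(network, keep) {
  out <- tibble::as_tibble(network)[keep, , drop = FALSE]
  if (inherits(network, "tw_network3")) {
    new_network3(out, nodes = network_nodes(network),
                 metric = attr(network, "metric"))
  } else {
    new_network2(out, nodes = network_nodes(network),
                 metric = attr(network, "metric"))
  }
}

#' Union of two networks
#'
#' Merges the edge sets of two networks over the union of their node
#' sets. A 2-way edge and a 3-way hyperedge are distinct objects even
#' when their species overlap, so the union of a pairwise MST and a
#' best-edge 3-way network keeps both layers: the tree supplies global
#' connectivity, the hyperedges local modularity. Identical duplicate
#' edges are merged keeping one copy; the same edge appearing with two
#' different weights is an error.
#'
#' @param a,b networks (`tw_network2`, `tw_network3`, or mixed).
#' @return If `a` and `b` have the same arity, that network kind;
#'   otherwise a mixed network: a tibble with columns `species_a`,
#'   `species_b`, `species_c` (`NA` for pairwise edges), `weight` and
#'   `kind` (`"pw"`/`"tw"`), class `tw_network_mixed`.
#' @export
union_networks <- function(a, b) {
  nodes <- sort(union(network_nodes(a), network_nodes(b)))
  arity <- function(x) if (inherits(x, "tw_network3")) 3L
    else if (inherits(x, "tw_network2")) 2L
    else if ("kind" %in% names(x)) 0L  # mixed
    else if ("species_c" %in% names(x)) 3L else 2L
  to_mixed <- function(x) {
    tb <- tibble::as_tibble(x)
    if (!"kind" %in% names(tb)) {
      if (!"species_c" %in% names(tb)) tb$species_c <- NA_character_
      tb$kind <- ifelse(is.na(tb$species_c), "pw", "tw")
    }
    tb[c("species_a", "species_b", "species_c", "weight", "kind")]
  }
  same_arity <- arity(a) == arity(b) && arity(a) > 0
  merged <- dplyr::bind_rows(to_mixed(a), to_mixed(b))
  key <- paste(merged$kind, edge_key(merged))
  dup <- duplicated(key)
  for (k in unique(key[dup])) {
    w <- unique(merged$weight[key == k])
    if (length(w) > 1) {
      abort(sprintf("edge '%s' appears with conflicting weights (%s).",
                    k, paste(format(w), collapse = ", ")))
    }
  }
  merged <- merged[!dup, , drop = FALSE]
  if (same_arity) {
    if (arity(a) == 3L) new_network3(merged, nodes = nodes)
    else new_network2(merged, nodes = nodes)
  } else {
    structure(merged, nodes = nodes,
              class = c("tw_network_mixed", class(tibble::tibble())))
  }
}

#' @export
print.tw_network_mixed <- function(x, ...) {
  cat(sprintf("<mixed network> %d nodes, %d 2-way edges, %d 3-way hyperedges\n",
              length(network_nodes(x)), sum(x$kind == "pw"),
              sum(x$kind == "tw")))
  NextMethod()
}

#' @exportS3Method generics::glance
glance.tw_network_mixed <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(network_nodes(x)),
    n_edges2 = sum(x$kind == "pw"), n_edges3 = sum(x$kind == "tw"),
    mean_weight = mean(x$weight)
  )
}
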