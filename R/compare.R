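#' Per-genus inbound/outbound edge statistics
#'
#' Counts, for each genus, the edges whose members all lie inside the
#' genus (inbound) and the edges incident to the genus with at least one
#' member outside (outbound). For a 3-way hyperedge the inbound rule
#' extends directly: all three members must belong to the genus. Edges
#' touching a genus in neither role are not counted for it. Ratios are
#' smoothed with a pseudocount — `ratio_io = (inbound + 1)/(outbound + 1)`
#' and its reciprocal — so genera with no outbound (or no inbound) edges
#' still rank.
#'
#' @param network a `tw_network2` or `tw_network3`.
#' @param genus_of named character vector mapping every network species
#'   to its genus.
#' @return A tibble with one row per genus:
#'   `genus`, `inbound`, `outbound`, `ratio_io`, `ratio_oi`.
#' @export
genus_edge_stats <- function(network, genus_of) {
  cols <- intersect(c("species_a", "species_b", "species_c"), names(network))
  species <- network_nodes(network)
  unmapped <- setdiff(species, names(genus_of))
  if (length(unmapped) > 0) {
    abort(sprintf("species without genus annotation: %s",
                  paste(unmapped, collapse = ", ")))
  }
  genera <- sort(unique(unname(genus_of[species])))
  inbound <- setNames(integer(length(genera)), genera)
  outbound <- inbound
  if (nrow(network) > 0) {
    mem <- as.matrix(tibble::as_tibble(network)[cols])
    for (e in seq_len(nrow(mem))) {
      gs <- unique(unname(genus_of[stats::na.omit(mem[e, ])]))
      if (length(gs) == 1) {
        inbound[gs] <- inbound[gs] + 1L
      } else {
        outbound[gs] <- outbound[gs] + 1L
      }
    }
  }
  tibble::tibble(
    genus = genera,
    inbound = as.integer(inbound), outbound = as.integer(outbound),
    ratio_io = (inbound + 1) / (outbound + 1),
    ratio_oi = (outbound + 1) / (inbound + 1)
  )
}

#' Disagreement between 2-way and 3-way genus topology
#'
#' Quantifies how differently a genus sits in a pairwise network versus a
#' triplet network. For each genus the inbound/outbound edge ratio (and
#' its reciprocal) is computed in both networks with
#' [genus_edge_stats()]; ratios are ranked within each network
#' (descending, average ranks on ties) and the disagreement score is the
#' absolute rank difference: `D_oi` for the inbound/outbound ratio,
#' `D_io` for the reciprocal. Large scores flag genera whose local
#' modularity changes between the two network types — e.g. a genus pair
#' linked by many cross-genus triplets that pairwise similarity does not
#' see.
#'
#' Typically `net2` is the best-edge pairwise network and `net3` the
#' best-edge (or thresholded) triplet network, but any pair over the same
#' species may be supplied.
#'
#' @param net2 a `tw_network2`.
#' @param net3 a `tw_network3`.
#' @param genus_of named character vector, species -> genus, covering
#'   both networks.
#' @return A tibble with one row per genus: the per-network counts
#'   (`inbound2`, `outbound2`, `inbound3`, `outbound3`) and scores
#'   `D_oi`, `D_io`.
#' @export
disagreement_scores <- function(net2, net3, genus_of) {
  s2 <- genus_edge_stats(net2, genus_of)
  s3 <- genus_edge_stats(net3, genus_of)
  genera <- sort(union(s2$genus, s3$genus))
  if (length(genera) < 2) {
    abort("ranking needs at least 2 genera.")
  }
  s2 <- s2[match(genera, s2$genus), ]
  s3 <- s3[match(genera, s3$genus), ]
  rank_desc <- function(v) rank(-v, ties.method = "average")
  tibble::tibble(
    genus = genera,
    inbound2 = s2$inbound, outbound2 = s2$outbound,
    inbound3 = s3$inbound, outbound3 = s3$outbound,
    D_oi = abs(rank_desc(s2$ratio_io) - rank_desc(s3$ratio_io)),
    D_io = abs(rank_desc(s2$ratio_oi) - rank_desc(s3$ratio_oi))
  )
}
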