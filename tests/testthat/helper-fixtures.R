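# Shared fixture builders and independent oracles. Everything is generated
# in code; no fixture files.

tiny_sf <- function() {
  sf_matrix(matrix(c(2L, 0L,
                     1L, 1L,
                     0L, 3L), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("f", 1:3), c("spA", "spB"))))
}

random_sf <- function(n_fam, n_sp, seed, max_count = 5) {
  withr::with_seed(seed, {
    counts <- matrix(sample(0:max_count, n_fam * n_sp, replace = TRUE),
                     n_fam, n_sp,
                     dimnames = list(paste0("f", seq_len(n_fam)),
                                     paste0("s", seq_len(n_sp))))
    sf_matrix(counts)
  })
}

# random connected weighted 2-way network: a random spanning tree plus a few
# extra edges, weights U(0, 1)
random_connected_net <- function(n_nodes, extra_edges, seed) {
  withr::with_seed(seed, {
    nodes <- paste0("n", seq_len(n_nodes))
    edges <- list()
    perm <- sample(nodes)
    for (i in seq_len(n_nodes - 1)) {
      pick <- sample(i, 1)
      edges[[i]] <- sort(c(perm[i + 1], perm[pick]))
    }
    all_pairs <- combn(sort(nodes), 2)
    key <- vapply(edges, paste, character(1), collapse = "|")
    avail <- which(!paste(all_pairs[1, ], all_pairs[2, ], sep = "|") %in% key)
    if (extra_edges > 0 && length(avail) > 0) {
      take <- sample(avail, min(extra_edges, length(avail)))
      edges <- c(edges, lapply(take, function(k) all_pairs[, k]))
    }
    em <- do.call(rbind, edges)
    new_network2(
      tibble::tibble(species_a = em[, 1], species_b = em[, 2],
                     weight = runif(nrow(em))),
      nodes = nodes)
  })
}

# brute-force maximum spanning tree weight by enumerating all (n-1)-edge
# subsets and keeping those that span without a cycle
brute_force_mst_weight <- function(net) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  m <- nrow(net)
  if (m < n - 1) return(NA_real_)
  best <- -Inf
  for (subset in asplit(combn(m, n - 1), 2)) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    ok <- TRUE
    for (e in subset) {
      ra <- find(match(net$species_a[e], nodes))
      rb <- find(match(net$species_b[e], nodes))
      if (ra == rb) {
        ok <- FALSE
        break
      }
      parent[ra] <- rb
    }
    if (ok) best <- max(best, sum(net$weight[subset]))
  }
  best
}

# per-genus membership count of a hyperedge tibble row matrix
genus_span <- function(net, genus_of) {
  cols <- intersect(c("species_a", "species_b", "species_c"), names(net))
  apply(as.matrix(tibble::as_tibble(net)[cols]), 1, function(r) {
    length(unique(genus_of[stats::na.omit(r)]))
  })
}
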