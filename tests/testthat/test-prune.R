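toy_net2 <- function(weights, nodes = NULL) {
  n <- length(weights) + 1
  labels <- paste0("n", seq_len(n))
  new_network2(
    tibble::tibble(species_a = labels[-n], species_b = labels[-1],
                   weight = weights),
    nodes = nodes %||% labels)
}

test_that("threshold pruning keeps exactly the edges at or above t", {
  net <- toy_net2(c(0.74, 0.75, 0.76, 0.9))
  out <- prune_threshold(net, 0.76)
  expect_equal(nrow(out), 2)
  expect_setequal(out$weight, c(0.76, 0.9))
  expect_identical(network_nodes(out), network_nodes(net))  # isolated kept
  expect_equal(nrow(prune_threshold(net, 0)), 4)
  # boundary semantics: >= t, so 0.75 survives t = 0.75 but not t = 0.76
  expect_true(0.75 %in% prune_threshold(net, 0.75)$weight)
  expect_false(0.75 %in% prune_threshold(net, 0.76)$weight)
  expect_error(prune_threshold(net, 1.5), "\\[0, 1\\]")
  rep <- prune_report(out)
  expect_equal(rep$edges_before, 4)
  expect_equal(rep$edges_after, 2)
})

test_that("thresholding a triplet network at 0.76 leaves only non-empty 3-way intersections", {
  for (seed in 1:3) {
    m <- random_sf(12, 6, seed = seed, max_count = 3)
    for (metric in c("sorensen", "czekanowski")) {
      kept <- prune_threshold(build_network3(m, metric), 0.76)
      for (e in seq_len(nrow(kept))) {
        v <- venn_counts(unclass(m)[, kept$species_a[e]],
                         unclass(m)[, kept$species_b[e]],
                         unclass(m)[, kept$species_c[e]])
        expect_gt(v$abc, 0)
      }
    }
  }
})

test_that("best-x keeps each node's strongest incident edges", {
  net <- new_network2(
    tibble::tibble(species_a = c("a", "a", "a"),
                   species_b = c("b", "c", "d"),
                   weight = c(0.9, 0.8, 0.7)),
    nodes = letters[1:4])
  out <- prune_best_edges(net, 2)
  # a keeps 0.9/0.8; b, c, d each keep their only edge, so 0.7 survives too
  expect_equal(sort(out$weight), c(0.7, 0.8, 0.9))
  star <- prune_best_edges(net, 1)
  expect_true(0.9 %in% star$weight)
  expect_equal(prune_report(star)$strategy, "best_x")
})

test_that("best-x with x at least the max degree is the identity", {
  net <- random_connected_net(6, extra_edges = 4, seed = 8)
  out <- prune_best_edges(net, x = nrow(net))
  expect_equal(tidy(out), tidy(net))
})

test_that("best-x agrees with a brute-force per-node union", {
  for (seed in 1:10) {
    net <- random_connected_net(6, extra_edges = 5, seed = 100 + seed)
    for (x in 1:3) {
      out <- prune_best_edges(net, x)
      keep <- rep(FALSE, nrow(net))
      for (node in network_nodes(net)) {
        inc <- which(net$species_a == node | net$species_b == node)
        inc <- inc[order(-net$weight[inc])]
        keep[inc[seq_len(min(x, length(inc)))]] <- TRUE
      }
      # weights are continuous so ties have probability zero
      expect_setequal(
        paste(out$species_a, out$species_b),
        paste(net$species_a[keep], net$species_b[keep]))
    }
  }
})

test_that("best-x on hyperedges keeps an edge if any member ranks it", {
  net3 <- new_network3(
    tibble::tibble(species_a = c("a", "a"), species_b = c("b", "b"),
                   species_c = c("c", "d"), weight = c(0.9, 0.5)),
    nodes = letters[1:4])
  out <- prune_best_edges(net3, 1)
  expect_equal(nrow(out), 2)  # d's only edge is the 0.5 one
})

test_that("maximum spanning tree picks the heaviest backbone", {
  tri <- new_network2(
    tibble::tibble(species_a = c("a", "a", "b"), species_b = c("b", "c", "c"),
                   weight = c(0.9, 0.8, 0.5)),
    nodes = c("a", "b", "c"))
  mst <- max_spanning_tree(tri)
  expect_setequal(mst$weight, c(0.9, 0.8))
  path <- toy_net2(c(0.3, 0.9, 0.2))
  expect_equal(tidy(max_spanning_tree(path)), tidy(path))  # already a tree
})

test_that("maximum spanning tree weight matches exhaustive enumeration and igraph", {
  for (seed in 1:20) {
    net <- random_connected_net(sample(4:7, 1) + 0, extra_edges = 3,
                                seed = 200 + seed)
    mst <- max_spanning_tree(net)
    n <- length(network_nodes(net))
    expect_equal(nrow(mst), n - 1)
    expect_equal(sum(mst$weight), brute_force_mst_weight(net))
    g <- igraph::graph_from_data_frame(
      tidy(net)[c("species_a", "species_b", "weight")], directed = FALSE)
    ig <- igraph::mst(g, weights = 1 - igraph::E(g)$weight)
    expect_equal(sum(mst$weight), sum(igraph::E(ig)$weight))
  }
})

test_that("disconnected networks yield a maximum spanning forest", {
  net <- new_network2(
    tibble::tibble(species_a = c("a", "c"), species_b = c("b", "d"),
                   weight = c(0.4, 0.6)),
    nodes = letters[1:5])  # e isolated
  f <- max_spanning_tree(net)
  expect_equal(nrow(f), 2)
  expect_identical(network_nodes(f), letters[1:5])
})

test_that("network unions merge edge sets and police weight conflicts", {
  a <- toy_net2(c(0.5, 0.6))
  b <- new_network2(
    tibble::tibble(species_a = "n1", species_b = "n3", weight = 0.7),
    nodes = c("n1", "n3"))
  u <- union_networks(a, b)
  expect_equal(nrow(u), 3)
  expect_equal(nrow(union_networks(a, a)), nrow(a))  # idempotent
  conflict <- new_network2(
    tibble::tibble(species_a = "n1", species_b = "n2", weight = 0.99),
    nodes = c("n1", "n2"))
  expect_error(union_networks(a, conflict), "conflicting weights")
})

test_that("MST plus best-edge hyperedges forms a connected mixed backbone", {
  m <- generate_sf(synthetic_config(seed = 5))
  mst <- max_spanning_tree(build_network2(m))
  best3 <- prune_best_edges(build_network3(m), 2)
  u <- union_networks(mst, best3)
  expect_s3_class(u, "tw_network_mixed")
  expect_equal(sum(u$kind == "pw"), ncol(m) - 1)
  expect_equal(sum(u$kind == "tw"), nrow(best3))
  pw <- u[u$kind == "pw", ]
  g <- igraph::graph_from_data_frame(pw[c("species_a", "species_b")],
                                     directed = FALSE,
                                     vertices = network_nodes(u))
  expect_true(igraph::is_connected(g))
})
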