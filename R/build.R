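#' Weighted species networks as tibbles
#'
#' 2-way networks are tibbles with columns `species_a`, `species_b`,
#' `weight` (one row per unordered pair, members in lexicographic order);
#' 3-way networks add `species_c` (one row per unordered triplet). Both
#' carry the full node set as an attribute so isolated species survive
#' pruning, plus the metric used to weight edges.
#'
#' @param edges a tibble of edges.
#' @param nodes character vector of all species in the network.
#' @param metric optional metric label (`"sorensen"`/`"czekanowski"`).
#' @name network_classes
NULL

new_network2 <- function(edges, nodes, metric = NULL) {
  edges <- tibble::as_tibble(edges)[c("species_a", "species_b", "weight")]
  structure(edges, nodes = nodes, metric = metric,
            class = c("tw_network2", class(tibble::tibble())))
}

new_network3 <- function(edges, nodes, metric = NULL) {
  edges <- tibble::as_tibble(edges)[
    c("species_a", "species_b", "species_c", "weight")]
  structure(edges, nodes = nodes, metric = metric,
            class = c("tw_network3", class(tibble::tibble())))
}

#' Network node set
#'
#' @param network a `tw_network2`, `tw_network3` or mixed network.
#' @return Character vector of species labels, including isolated ones.
#' @export
network_nodes <- function(network) {
  nd <- attr(network, "nodes")
  if (!is.null(nd)) return(nd)
  cols <- intersect(c("species_a", "species_b", "species_c"), names(network))
  sort(unique(stats::na.omit(unlist(network[cols], use.names = FALSE))))
}

sort_pair <- function(a, b) {
  swap <- b < a
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

#' Build the all-vs-all 2-way similarity network
#'
#' Computes the chosen similarity index between every pair of species
#' columns of an SF matrix, yielding a complete weighted graph with
#' `choose(n, 2)` edges.
#'
#' @param matrix an [sf_matrix()] with at least 2 species.
#' @param metric `"sorensen"` (presence/absence) or `"czekanowski"`
#'   (raw counts).
#' @return A `tw_network2` tibble (`species_a`, `species_b`, `weight`).
#' @examples
#' m <- generate_sf(synthetic_config(seed = 1))
#' build_network2(m, "sorensen")
#' @export
build_network2 <- function(matrix, metric = c("sorensen", "czekanowski")) {
  metric <- match.arg(metric)
  stopifnot(inherits(matrix, "sf_matrix"))
  n <- ncol(matrix)
  if (n < 2) abort("need at least 2 species to build a 2-way network.")
  counts <- unclass(matrix)
  if (metric == "sorensen") counts <- (counts >= 1L) + 0L
  sp <- colnames(counts)
  tot <- colSums(counts)
  pairs <- utils::combn(n, 2)
  w <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ratio0(2 * sum(pmin(counts[, i], counts[, j])), tot[i] + tot[j])
  }, numeric(1))
  ab <- sort_pair(sp[pairs[1, ]], sp[pairs[2, ]])
  new_network2(
    tibble::tibble(species_a = ab$a, species_b = ab$b, weight = w),
    nodes = sp, metric = metric
  )
}

#' Build the all-triplets 3-way similarity network
#'
#' Computes the 3-way index between every triplet of species columns of an
#' SF matrix, yielding a complete 3-uniform hypergraph with
#' `choose(n, 3)` hyperedges. Pairwise minima sums are cached so the
#' per-triplet work is a single vectorised pass, keeping the full
#' all-triplets network for dozens of species comfortably in memory.
#'
#' @inheritParams build_network2
#' @return A `tw_network3` tibble
#'   (`species_a`, `species_b`, `species_c`, `weight`).
#' @examples
#' m <- generate_sf(synthetic_config(seed = 1))
#' net3 <- build_network3(m, "sorensen")
#' nrow(net3) == choose(ncol(m), 3)
#' @export
build_network3 <- function(matrix, metric = c("sorensen", "czekanowski")) {
  metric <- match.arg(metric)
  stopifnot(inherits(matrix, "sf_matrix"))
  n <- ncol(matrix)
  if (n < 3) abort("need at least 3 species to build a 3-way network.")
  counts <- unclass(matrix)
  if (metric == "sorensen") counts <- (counts >= 1L) + 0L
  storage.mode(counts) <- "double"
  sp <- colnames(counts)
  tot <- colSums(counts)

  # pairwise sum-of-minima cache
  m2 <- base::matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    m2[i, rest] <- colSums(pmin(counts[, rest, drop = FALSE], counts[, i]))
  }
  m2 <- m2 + t(m2)

  idx <- 0L
  total <- choose(n, 3)
  out_i <- integer(total); out_j <- integer(total); out_k <- integer(total)
  out_w <- numeric(total)
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      mij <- pmin(counts[, i], counts[, j])
      ks <- (j + 1):n
      min3 <- colSums(pmin(counts[, ks, drop = FALSE], mij))
      num <- m2[i, j] + m2[i, ks] + m2[j, ks] - min3
      den <- tot[i] + tot[j] + tot[ks]
      w <- ifelse(den == 0, 0, 1.5 * num / den)
      slot <- idx + seq_along(ks)
      out_i[slot] <- i; out_j[slot] <- j; out_k[slot] <- ks
      out_w[slot] <- w
      idx <- idx + length(ks)
    }
  }
  trip <- apply(cbind(sp[out_i], sp[out_j], sp[out_k]), 1, sort)
  new_network3(
    tibble::tibble(species_a = trip[1, ], species_b = trip[2, ],
                   species_c = trip[3, ], weight = out_w),
    nodes = sp, metric = metric
  )
}

#' Read and write edge-list files
#'
#' Edge lists are TSV: `speciesA speciesB weight` for 2-way networks and
#' `speciesA speciesB speciesC weight` for 3-way networks, members in
#' lexicographic order and weights printed with 6 decimal places. Lines
#' starting with `#` are treated as comments.
#'
#' @param network a `tw_network2` or `tw_network3`.
#' @param path file path.
#' @param header optional character vector of comment lines (written
#'   prefixed with `#`).
#' @export
write_edgelist <- function(network, path, header = NULL) {
  is3 <- inherits(network, "tw_network3") || "species_c" %in% names(network)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  cols <- if (is3) c("species_a", "species_b", "species_c") else
    c("species_a", "species_b")
  body <- do.call(paste, c(unname(as.list(network[cols])),
                           list(sprintf("%.6f", network$weight), sep = "\t")))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_edgelist
#' @param n_members 2 or 3: arity of the edges in the file.
#' @export
read_edgelist <- function(path, n_members = 2) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) > 0 && any(lengths(parts) != n_members + 1)) {
    abort(sprintf("'%s': expected %d tab-separated fields per line.",
                  path, n_members + 1))
  }
  fld <- function(i) vapply(parts, `[[`, character(1), i)
  if (length(parts) == 0) {
    edges <- if (n_members == 3) {
      tibble::tibble(species_a = character(), species_b = character(),
                     species_c = character(), weight = numeric())
    } else {
      tibble::tibble(species_a = character(), species_b = character(),
                     weight = numeric())
    }
  } else if (n_members == 3) {
    edges <- tibble::tibble(species_a = fld(1), species_b = fld(2),
                            species_c = fld(3), weight = as.numeric(fld(4)))
  } else {
    edges <- tibble::tibble(species_a = fld(1), species_b = fld(2),
                            weight = as.numeric(fld(3)))
  }
  if (n_members == 3) new_network3(edges, nodes = network_nodes(edges))
  else new_network2(edges, nodes = network_nodes(edges))
}

#' @exportS3Method generics::tidy
tidy.tw_network2 <- function(x, ...) {
  strip_net_attrs(tibble::as_tibble(x))
}

strip_net_attrs <- function(x) {
  for (a in c("nodes", "metric", "prune_report")) attr(x, a) <- NULL
  x
}

#' @exportS3Method generics::tidy
tidy.tw_network3 <- function(x, ...) {
  strip_net_attrs(tibble::as_tibble(x))
}

#' @exportS3Method generics::glance
glance.tw_network2 <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(network_nodes(x)), n_edges = nrow(x),
    mean_weight = mean(x$weight), max_weight = max(x$weight, -Inf),
    metric = attr(x, "metric") %||% NA_character_
  )
}

#' @exportS3Method generics::glance
glance.tw_network3 <- glance.tw_network2

#' @export
print.tw_network2 <- function(x, ...) {
  cat(sprintf("<2-way network> %d nodes, %d edges%s\n",
              length(network_nodes(x)), nrow(x), metric_tag(x)))
  NextMethod()
}

#' @export
print.tw_network3 <- function(x, ...) {
  cat(sprintf("<3-way network> %d nodes, %d hyperedges%s\n",
              length(network_nodes(x)), nrow(x), metric_tag(x)))
  NextMethod()
}

metric_tag <- function(x) {
  m <- attr(x, "metric")
  if (is.null(m)) "" else sprintf(" (%s)", m)
}
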