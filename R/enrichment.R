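#' Gene-family enrichment by Fisher's exact test
#'
#' Tests every (family, species) cell of the SF matrix for over-representation
#' of that family in that species. The 2x2 table for family \eqn{i} in
#' species \eqn{j} is gene-level:
#' \tabular{lcc}{
#'             \tab in species j \tab elsewhere \cr
#'  family i   \tab k            \tab K - k     \cr
#'  other fams \tab n - k        \tab N - K - n + k
#' }
#' with \eqn{N} the total gene count, \eqn{K} the family's total, \eqn{n}
#' the species' total and \eqn{k} the cell count. The one-sided
#' (enrichment-direction) Fisher p-value is the hypergeometric upper tail
#' \eqn{P(X \ge k)}. With `level = "presence"` the same construction is
#' applied to the binarized matrix, testing over-representation of family
#' presence instead of gene counts.
#'
#' @param matrix an [sf_matrix()] with at least 2 species and 2 families.
#' @param level `"gene"` (default, raw counts) or `"presence"`.
#' @return A tibble with one row per (family, species):
#'   `family`, `species`, `k`, `K`, `n`, `N`, `p_value`.
#' @examples
#' m <- sf_matrix(matrix(c(3L, 1L, 1L, 3L), 2,
#'                dimnames = list(c("f1", "f2"), c("a", "b"))))
#' fisher_enrichment(m)
#' @export
fisher_enrichment <- function(matrix, level = c("gene", "presence")) {
  level <- match.arg(level)
  stopifnot(inherits(matrix, "sf_matrix"))
  if (ncol(matrix) < 2 || nrow(matrix) < 2) {
    abort("need at least 2 species and 2 families.")
  }
  counts <- unclass(matrix)
  if (level == "presence") counts <- (counts >= 1L) + 0L
  N <- sum(counts)
  if (N == 0) abort("degenerate matrix: total gene count is zero.")
  K <- rowSums(counts)
  n <- colSums(counts)
  grid <- expand.grid(fi = seq_len(nrow(counts)), sj = seq_len(ncol(counts)))
  k <- counts[cbind(grid$fi, grid$sj)]
  Kv <- K[grid$fi]
  nv <- n[grid$sj]
  # one-sided Fisher p for the 2x2 table == hypergeometric upper tail
  p <- phyper(k - 1, Kv, N - Kv, nv, lower.tail = FALSE)
  tibble::tibble(
    family = rownames(counts)[grid$fi],
    species = colnames(counts)[grid$sj],
    k = as.integer(k), K = as.integer(Kv), n = as.integer(nv),
    N = as.integer(N), p_value = pmin(p, 1)
  )
}

#' Holm-Bonferroni step-down correction
#'
#' Classic step-down control of the family-wise error rate: p-values are
#' sorted ascending and \eqn{p_{(i)}} is rejected while
#' \eqn{p_{(i)} \le \alpha / (m - i + 1)}, stopping at the first failure.
#' Decisions are returned in the input order. Holm rejects everything
#' plain Bonferroni rejects, and possibly more.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate, default 0.05.
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @examples
#' holm_bonferroni(c(0.01, 0.02, 0.04))  # all TRUE
#' holm_bonferroni(c(0.04, 0.04, 0.04))  # all FALSE
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    abort("p-values must lie in [0, 1].")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1).")
  }
  p.adjust(p, method = "holm") <= alpha
}

#' Enrichment with multiplicity correction
#'
#' Runs [fisher_enrichment()] and appends Holm-Bonferroni decisions. The
#' correction is applied over all (family x species) tests jointly by
#' default; `scope = "per_species"` corrects within each species' family
#' tests instead.
#'
#' @inheritParams fisher_enrichment
#' @inheritParams holm_bonferroni
#' @param scope `"global"` (default) or `"per_species"`.
#' @return The [fisher_enrichment()] tibble with a logical `significant`
#'   column, class `tw_enrichment`.
#' @export
enrich_families <- function(matrix, alpha = 0.05,
                            scope = c("global", "per_species"),
                            level = c("gene", "presence")) {
  scope <- match.arg(scope)
  rec <- fisher_enrichment(matrix, level = level)
  rec$significant <- if (scope == "global") {
    holm_bonferroni(rec$p_value, alpha)
  } else {
    unsplit(lapply(split(rec$p_value, rec$species), holm_bonferroni,
                   alpha = alpha), rec$species)
  }
  structure(rec, alpha = alpha, scope = scope,
            class = c("tw_enrichment", class(tibble::tibble())))
}

#' Shared-enriched-family bipartite network
#'
#' Keeps the gene families significantly enriched in more than one species
#' ("shared-enriched families") and connects each to the species in which
#' it is enriched, giving a bipartite family-species network. Species
#' with no retained family remain as isolated nodes; every family node
#' has degree at least 2 by construction.
#'
#' @param records output of [enrich_families()] (or any tibble with
#'   `family`, `species`, `significant`).
#' @return A list of class `tw_bipartite` with tibbles `edges`
#'   (`family`, `species`) and `nodes` (`node`, `kind`).
#' @export
shared_enriched_network <- function(records) {
  stopifnot(all(c("family", "species", "significant") %in% names(records)))
  sig <- dplyr::filter(records, .data$significant)
  shared <- dplyr::filter(
    dplyr::count(sig, .data$family), .data$n >= 2)$family
  edges <- dplyr::arrange(
    dplyr::select(
      dplyr::filter(sig, .data$family %in% shared),
      "family", "species"),
    .data$family, .data$species)
  species <- sort(unique(records$species))
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = species, kind = "species"),
    tibble::tibble(node = sort(unique(edges$family)), kind = "family")
  )
  structure(list(edges = tibble::as_tibble(edges), nodes = nodes),
            class = "tw_bipartite")
}

#' @export
print.tw_bipartite <- function(x, ...) {
  cat(sprintf(
    "<bipartite enrichment network> %d species, %d shared-enriched families, %d edges\n",
    sum(x$nodes$kind == "species"), sum(x$nodes$kind == "family"),
    nrow(x$edges)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tw_bipartite <- function(x, ...) {
  x$edges
}

#' @exportS3Method generics::glance
glance.tw_enrichment <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x), n_significant = sum(x$significant),
    alpha = attr(x, "alpha"), scope = attr(x, "scope")
  )
}
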