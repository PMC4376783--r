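#' Pairwise and triplet similarity indices
#'
#' The Sorensen index measures presence/absence overlap between gene-family
#' profiles; the Czekanowski index is its quantitative analogue computed on
#' raw gene counts. Both have a triplet form used to weight 3-way network
#' hyperedges:
#' \deqn{S_2(X, Y) = \frac{2\sum_i \min(X_{Bi}, Y_{Bi})}{\sum_i (X_{Bi} + Y_{Bi})}}
#' \deqn{S_3(X, Y, Z) = \frac{3}{2}\,\frac{ab + ac + bc - abc}{a + b + c}}
#' where \eqn{a, b, c} are per-species family totals, \eqn{ab, ac, bc} the
#' pairwise shared counts and \eqn{abc} the triple-shared count of the
#' binarized profiles. The Czekanowski forms use the identical expressions
#' with elementwise minima of the raw counts. All four indices lie in
#' `[0, 1]`; the triplet forms are invariant under argument permutation.
#'
#' Two results make these indices useful for pruning: if a species triplet
#' shares no family (\eqn{abc = 0}) then \eqn{S_3 \le 3/4}, and likewise
#' \eqn{C_3 \le 3/4} whenever \eqn{\sum_i \min(X_i, Y_i, Z_i) = 0}. Any
#' threshold strictly above 0.75 therefore retains only triplets with a
#' genuine three-way intersection; see [prune_threshold()].
#'
#' When all profiles involved are empty the denominator vanishes; the index
#' is defined as 0 (empty genomes share nothing, and pruning treats a
#' 0-weight edge as absent).
#'
#' @param x,y,z non-negative count vectors of equal length (one SF-matrix
#'   column each). Sorensen indices binarize internally.
#' @return A similarity in `[0, 1]`.
#' @examples
#' sorensen2(c(1, 1, 0), c(0, 1, 1))            # 0.5
#' sorensen3(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1)) # 0.75, the abc = 0 bound
#' czekanowski2(c(2, 0, 1), c(1, 1, 0))          # 0.4
#' @name similarity_indices
NULL

check_profiles <- function(...) {
  vs <- list(...)
  n <- lengths(vs)
  if (length(unique(n)) != 1) {
    abort(sprintf("profile length mismatch: %s.", paste(n, collapse = " vs ")))
  }
  if (any(vapply(vs, function(v) any(v < 0), logical(1)))) {
    abort("profiles must be non-negative.")
  }
  invisible(vs)
}

ratio0 <- function(num, den) {
  if (den == 0) 0 else num / den
}

#' @rdname similarity_indices
#' @export
sorensen2 <- function(x, y) {
  check_profiles(x, y)
  czekanowski2(as.integer(x >= 1), as.integer(y >= 1))
}

#' @rdname similarity_indices
#' @export
sorensen3 <- function(x, y, z) {
  check_profiles(x, y, z)
  czekanowski3(as.integer(x >= 1), as.integer(y >= 1), as.integer(z >= 1))
}

#' @rdname similarity_indices
#' @export
czekanowski2 <- function(x, y) {
  check_profiles(x, y)
  ratio0(2 * sum(pmin(x, y)), sum(x) + sum(y))
}

#' @rdname similarity_indices
#' @export
czekanowski3 <- function(x, y, z) {
  check_profiles(x, y, z)
  num <- sum(pmin(x, y)) + sum(pmin(x, z)) + sum(pmin(y, z)) -
    sum(pmin(x, pmin(y, z)))
  ratio0(1.5 * num, sum(x) + sum(y) + sum(z))
}

#' Pairwise gene similarity score from reciprocal BLAST E-values
#'
#' Converts the two E-values of a reciprocal best hit between genes
#' \eqn{a} and \eqn{b} into a single non-negative similarity score, the
#' edge weight used by TribeMCL-style gene-family clustering. The default
#' convention is \eqn{-\log_{10}((E_{ab} + E_{ba})/2)}, clamped at
#' `ceiling` so aligner-reported underflows (`E = 0`) stay finite. The
#' literal signed base-2 form is available via `convention = "log2_mean"`.
#'
#' @param e_ab,e_ba E-values in `[0, 1]`, typically from reciprocal BLAST
#'   hits. Zero is accepted and clamped; negative values are an error.
#' @param convention `"neg_log10_mean"` (default) or `"log2_mean"`.
#' @param ceiling upper bound for the default convention's score.
#' @return A finite numeric score (non-negative under the default
#'   convention).
#' @examples
#' tribemcl_pair_score(1e-5, 1e-5)  # 5
#' tribemcl_pair_score(1, 1)        # 0
#' @export
tribemcl_pair_score <- function(e_ab, e_ba,
                                convention = c("neg_log10_mean", "log2_mean"),
                                ceiling = 200) {
  convention <- match.arg(convention)
  if (e_ab < 0 || e_ba < 0) abort("E-values must be non-negative.")
  m <- (e_ab + e_ba) / 2
  switch(convention,
    neg_log10_mean = if (m == 0) ceiling else min(-log10(m), ceiling),
    log2_mean = if (m == 0) -Inf else log2(m)
  )
}
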