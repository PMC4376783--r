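#' Species-family count matrices
#'
#' An `sf_matrix` holds gene-family content profiles for a set of species:
#' a non-negative integer matrix with gene families in rows and species in
#' columns, where entry \eqn{ij} is the number of genes of family \eqn{i}
#' found in species \eqn{j}. An optional genus annotation maps each species
#' to its genus, which downstream topology comparisons require.
#'
#' @param counts integer matrix, families x species, with complete dimnames.
#' @param genus optional named character vector mapping every species id
#'   (column name) to a genus label.
#'
#' @return An object of class `sf_matrix`: the count matrix with a `genus`
#'   attribute.
#' @examples
#' m <- sf_matrix(matrix(c(2L, 0L, 1L, 1L, 0L, 3L), nrow = 3, byrow = TRUE,
#'                dimnames = list(c("f1", "f2", "f3"), c("spA", "spB"))))
#' colSums(m)
#' @export
sf_matrix <- function(counts, genus = NULL) {
  if (!is.matrix(counts)) {
    counts <- as.matrix(counts)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have family row names and species column names.")
  }
  if (anyDuplicated(rownames(counts))) {
    abort("duplicate family ids in `counts` row names.")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("duplicate species ids in `counts` column names.")
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    abort("`counts` must be numeric with no missing values.")
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "cell [family '%s', species '%s'] is %s; counts must be non-negative integers.",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])
    ))
  }
  storage.mode(counts) <- "integer"
  if (!is.null(genus)) {
    genus <- validate_genus(genus, colnames(counts))
  }
  structure(counts, genus = genus, class = c("sf_matrix", "matrix", "array"))
}

validate_genus <- function(genus, species_ids) {
  if (is.data.frame(genus)) {
    genus <- setNames(as.character(genus[[2]]), as.character(genus[[1]]))
  }
  if (is.null(names(genus))) {
    abort("`genus` must be named by species id.")
  }
  missing_sp <- setdiff(names(genus), species_ids)
  if (length(missing_sp) > 0) {
    abort(sprintf(
      "genus map lists species absent from the matrix: %s",
      paste(missing_sp, collapse = ", ")
    ))
  }
  uncovered <- setdiff(species_ids, names(genus))
  if (length(uncovered) > 0) {
    abort(sprintf(
      "genus map does not cover species: %s",
      paste(uncovered, collapse = ", ")
    ))
  }
  genus[species_ids]
}

#' @export
print.sf_matrix <- function(x, ...) {
  cat(sprintf(
    "<sf_matrix> %d gene families x %d species%s\n",
    nrow(x), ncol(x),
    if (is.null(attr(x, "genus"))) "" else
      sprintf(" (%d genera)", length(unique(attr(x, "genus"))))
  ))
  print(head(unclass(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more families\n", nrow(x) - 6L))
  invisible(x)
}

#' Genus annotation of an sf_matrix
#'
#' @param x an [sf_matrix()].
#' @return Named character vector (species id -> genus), or `NULL`.
#' @export
genus_of <- function(x) {
  attr(x, "genus")
}

require_genus <- function(x) {
  g <- genus_of(x)
  if (is.null(g)) {
    abort("this operation needs genus annotations; supply `genus` to sf_matrix() or read_sf_matrix().")
  }
  g
}

#' Read and write species-family matrices
#'
#' The on-disk format is UTF-8 tab-separated text: a header row of species
#' ids (the first header cell is ignored), one row per gene family with the
#' family id in the first column and integer gene counts in the remaining
#' columns. The genus map is a two-column TSV with header
#' `species<TAB>genus`.
#'
#' @param path path to the SF matrix TSV.
#' @param genus_path optional path to the species-to-genus TSV.
#' @return [read_sf_matrix()] returns an [sf_matrix()]; row and column
#'   order are preserved from the file.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- sf_matrix(matrix(1:4, 2, dimnames = list(c("f1", "f2"), c("a", "b"))))
#' write_sf_matrix(m, tf)
#' identical(unclass(read_sf_matrix(tf)), unclass(m))
#' @export
read_sf_matrix <- function(path, genus_path = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#", fileEncoding = "UTF-8")
  if (ncol(tab) < 2) {
    abort(sprintf("'%s' does not look like an SF matrix: need a family id column plus species columns.", path))
  }
  fam <- tab[[1]]
  body <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "'%s': cell [family '%s', species '%s'] = '%s' is not a non-negative integer.",
      path, fam[bad[1, 1]], colnames(tab)[-1][bad[1, 2]],
      body[bad[1, , drop = FALSE]]
    ))
  }
  dimnames(num) <- list(fam, colnames(tab)[-1])
  genus <- if (!is.null(genus_path)) read_genus_map(genus_path)
  sf_matrix(num, genus = genus)
}

#' @rdname read_sf_matrix
#' @param x an [sf_matrix()] to write.
#' @export
write_sf_matrix <- function(x, path) {
  stopifnot(inherits(x, "sf_matrix"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("family", colnames(x)), collapse = "\t"), con)
  body <- cbind(rownames(x), apply(unclass(x), 2, as.character))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname read_sf_matrix
#' @export
read_genus_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#", fileEncoding = "UTF-8")
  if (ncol(tab) < 2) {
    abort(sprintf("'%s' is not a two-column species/genus table.", path))
  }
  setNames(tab[[2]], tab[[1]])
}

#' @rdname read_sf_matrix
#' @param genus named character vector (species -> genus) to write.
#' @export
write_genus_map <- function(genus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("species\tgenus", paste(names(genus), genus, sep = "\t")), con)
  invisible(path)
}

#' Presence/absence profiles
#'
#' Reduces gene counts to presence bits: bit \eqn{i} of a species' profile
#' is 1 exactly when the species has at least one gene of family \eqn{i}.
#' The Sorensen indices are computed on these binary profiles; the
#' Czekanowski indices use the raw counts.
#'
#' @param x an [sf_matrix()] or a non-negative numeric matrix/vector.
#' @return Same shape as the input, with entries in `{0, 1}`.
#' @examples
#' binarize(c(0, 1, 7))
#' @export
binarize <- function(x) {
  if (inherits(x, "sf_matrix")) {
    b <- unclass(x)
    b[] <- as.integer(b >= 1L)
    return(sf_matrix(b, genus = genus_of(x)))
  }
  if (any(x < 0)) abort("counts must be non-negative.")
  x_out <- x
  x_out[] <- as.integer(x >= 1)
  storage.mode(x_out) <- "integer"
  x_out
}

#' Venn region occupancy for a species triplet
#'
#' Decomposes the family universe of three presence/absence profiles into
#' the seven Venn regions: per-species totals (`a`, `b`, `c`), pairwise
#' intersections (`ab`, `ac`, `bc`), the triple intersection (`abc`) and
#' the three unique regions (`a_only`, `b_only`, `c_only`). These counts
#' are the set-theoretic form of the 3-way Sorensen index and the quantity
#' `abc` is what the 0.75 threshold theorem is about.
#'
#' @param x,y,z 0/1 (or count) vectors over the same family universe;
#'   counts are binarized first.
#' @return A one-row tibble with columns
#'   `a, b, c, ab, ac, bc, abc, a_only, b_only, c_only`.
#' @examples
#' venn_counts(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))
#' @export
venn_counts <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    abort("profiles must be over the same family universe (equal lengths).")
  }
  xb <- as.integer(x >= 1)
  yb <- as.integer(y >= 1)
  zb <- as.integer(z >= 1)
  ab <- sum(xb & yb)
  ac <- sum(xb & zb)
  bc <- sum(yb & zb)
  abc <- sum(xb & yb & zb)
  tibble::tibble(
    a = sum(xb), b = sum(yb), c = sum(zb),
    ab = ab, ac = ac, bc = bc, abc = abc,
    a_only = sum(xb & !yb & !zb),
    b_only = sum(yb & !xb & !zb),
    c_only = sum(zb & !xb & !yb)
  )
}

#' @exportS3Method generics::tidy
tidy.sf_matrix <- function(x, ...) {
  g <- genus_of(x)
  out <- tibble::as_tibble(as.data.frame.table(unclass(x),
                                               stringsAsFactors = FALSE))
  names(out) <- c("family", "species", "count")
  if (!is.null(g)) out$genus <- unname(g[out$species])
  out
}

#' @exportS3Method generics::glance
glance.sf_matrix <- function(x, ...) {
  tibble::tibble(
    n_families = nrow(x),
    n_species = ncol(x),
    n_genera = if (is.null(genus_of(x))) NA_integer_ else
      length(unique(genus_of(x))),
    total_genes = sum(x),
    occupancy = mean(unclass(x) >= 1L)
  )
}
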