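#' Hierarchical taxonomy objects
#'
#' A `taxonomy` is a rooted Linnean hierarchy over `T >= 2` levels with
#' operational taxonomic units (OTUs) at the tips (level 1) and exactly one
#' taxon at the uppermost level `T`.  It is stored as a flat classification
#' table: one row per OTU, one column per level, ordered from the lowest
#' level to the highest.  Taxa at each level are mutually exclusive, so every
#' taxon at level `t < T` has exactly one parent at level `t + 1`; the
#' constructor validates this and rejects a taxon name that appears under two
#' different parents at the same level.
#'
#' @param x a data frame or character matrix of the classification: one row
#'   per OTU, one column per taxonomic level from lowest (the OTU level
#'   itself, e.g. genus or species) to highest.  Row values are taxon names;
#'   the first column must hold the (unique) OTU names and the last column a
#'   single uppermost taxon.
#' @param levels optional character vector of level names, lowest first;
#'   defaults to the column names of `x`.
#'
#' @return an object of class `"taxonomy"`: a list with elements
#'   `classification` (character matrix, rows = OTUs, columns = levels) and
#'   `levels` (character vector of level names).
#'
#' @details Taxon identity is the pair (level, name): the same name may
#'   appear at two different levels, but within one level a name denotes a
#'   single taxon.  Homonymous taxa under different parents must therefore be
#'   spelled distinctly in the input.
#'
#' @examples
#' cls <- data.frame(
#'   genus  = c("Ga", "Ga", "Gb"),
#'   family = c("Fa", "Fa", "Fa"),
#'   order  = c("O", "O", "O")
#' )
#' tx <- taxonomy(cls)
#' taxon_counts(tx)
#' @export
taxonomy <- function(x, levels = NULL) {
  if (is.data.frame(x)) {
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) {
    stop("'x' must be a data frame or matrix (rows = OTUs, columns = levels)")
  }
  storage.mode(x) <- "character"
  if (is.null(levels)) {
    levels <- colnames(x)
  }
  if (is.null(levels)) {
    levels <- paste0("level", seq_len(ncol(x)))
  }
  if (length(levels) != ncol(x)) {
    stop("'levels' must name every column of the classification table")
  }
  colnames(x) <- levels
  rownames(x) <- unname(x[, 1L])
  obj <- structure(list(classification = x, levels = levels),
                   class = "taxonomy")
  validate_taxonomy(obj)
  obj
}

#' Validate a taxonomy object
#'
#' Checks all structural invariants: at least two levels and two OTUs, no
#' missing cells, unique OTU names, a single uppermost taxon, and a single
#' parent for every taxon at every level.
#'
#' @param tx a `taxonomy` object.
#' @return `tx`, invisibly; errors describe the first violated invariant.
#' @export
validate_taxonomy <- function(tx) {
  cls <- tx$classification
  if (nrow(cls) == 0L) stop("empty classification table")
  if (ncol(cls) < 2L) stop("a taxonomy needs at least 2 levels")
  if (nrow(cls) < 2L) stop("a taxonomy needs at least 2 OTUs")
  if (anyNA(cls) || any(!nzchar(cls))) {
    stop("classification table has missing cells")
  }
  otus <- cls[, 1L]
  if (anyDuplicated(otus)) {
    stop("duplicate OTU name(s): ",
         paste(unique(otus[duplicated(otus)]), collapse = ", "))
  }
  if (length(unique(cls[, ncol(cls)])) != 1L) {
    stop("all OTUs must belong to a single taxon at the uppermost level")
  }
  for (t in seq_len(ncol(cls) - 1L)) {
    pairs <- unique(cls[, c(t, t + 1L), drop = FALSE])
    dup <- pairs[duplicated(pairs[, 1L]), 1L]
    if (length(dup)) {
      stop(sprintf(
        "taxon '%s' at level '%s' is claimed under two parents at level '%s'",
        dup[1L], colnames(cls)[t], colnames(cls)[t + 1L]))
    }
  }
  invisible(tx)
}

#' @export
print.taxonomy <- function(x, ...) {
  ct <- taxon_counts(x)
  cat(sprintf("Taxonomy: %d OTUs, %d levels\n", ct[1L], length(x$levels)))
  cat("Taxa per level:\n")
  print(ct)
  invisible(x)
}

#' Number of taxa at each level
#'
#' @param tx a `taxonomy` object.
#' @return named integer vector `S_t` for `t = 1..T` (lowest level first);
#'   the first entry is the number of OTUs `S` and the last is always 1.
#' @examples
#' taxon_counts(balanced_tree(c(9, 6, 3, 1)))
#' @export
taxon_counts <- function(tx) {
  cls <- tx$classification
  ct <- vapply(seq_len(ncol(cls)),
               function(t) length(unique(cls[, t])), integer(1))
  names(ct) <- tx$levels
  ct
}

#' OTU names of a taxonomy
#'
#' @param tx a `taxonomy` object.
#' @return character vector of the level-1 taxon (OTU) names, in table order.
#' @export
otu_names <- function(tx) {
  unname(tx$classification[, 1L])
}

#' Restrict a master taxonomy to a sample of OTUs
#'
#' Returns the taxonomic tree spanned by the sampled OTUs: their rows of the
#' master classification, in the sample's order.  Internal taxa without
#' sampled descendants disappear automatically; the level structure is
#' preserved, so step lengths derived from the master still apply.
#'
#' @param master a `taxonomy` (the master list).
#' @param otus character vector of distinct OTU names, each present in
#'   `master`; at least 2.
#' @return a `taxonomy` with exactly the sampled OTUs.
#' @examples
#' m <- balanced_tree(c(9, 6, 3, 1))
#' prune_taxonomy(m, otu_names(m)[c(1, 9)])
#' @export
prune_taxonomy <- function(master, otus) {
  otus <- as.character(otus)
  if (anyDuplicated(otus)) stop("sample contains duplicated OTU names")
  missing <- setdiff(otus, otu_names(master))
  if (length(missing)) {
    stop("sample OTU(s) absent from master list: ",
         paste(missing, collapse = ", "))
  }
  if (length(otus) < 2L) stop("a sample needs at least 2 OTUs")
  taxonomy(master$classification[otus, , drop = FALSE], master$levels)
}

#' Insert a redundant level into a taxonomy
#'
#' Adds a new level just above `below_level` whose taxa copy the partition at
#' `below_level` one to one.  Under biodiversity-loss-proportional step
#' lengths the inserted step carries zero loss and zero length, so AvTD and
#' VarTD are unchanged; this operation exists to exercise that invariance.
#'
#' @param tx a `taxonomy`.
#' @param below_level integer level index in `1..T-1`; the copy is inserted
#'   between `below_level` and `below_level + 1`.
#' @param name name for the new level.
#' @return a `taxonomy` with `T + 1` levels.
#' @export
insert_redundant_level <- function(tx, below_level,
                                   name = paste0(tx$levels[below_level],
                                                 "_dup")) {
  T <- length(tx$levels)
  below_level <- as.integer(below_level)
  if (below_level < 1L || below_level >= T) {
    stop("'below_level' must be in 1..T-1")
  }
  cls <- tx$classification
  newcol <- paste0(cls[, below_level], "*")
  cls <- cbind(cls[, seq_len(below_level), drop = FALSE],
               newcol,
               cls[, (below_level + 1L):T, drop = FALSE])
  lv <- append(tx$levels, name, after = below_level)
  colnames(cls) <- lv
  taxonomy(cls, lv)
}
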