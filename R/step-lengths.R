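#' Step-length schemes for taxonomic distances
#'
#' The taxonomic distance between two OTUs is the shortest (unrooted) path
#' between them on the taxonomic tree: up from one OTU to the lowest level at
#' which they share an ancestor, then down to the other.  A step-length
#' scheme assigns a length `l_t` to the step between levels `t` and `t + 1`
#' (the same in both directions), so two OTUs first united at level `c` lie
#' at distance `2 * (l_1 + ... + l_{c-1})`.
#'
#' Standardized schemes scale the longest possible path — two OTUs that meet
#' only at the uppermost level `T`, i.e. `2(T - 1)` steps — to 100, which
#' makes analyses comparable across taxonomies with different numbers of
#' levels and robust to the insertion of redundant ranks.
#'
#' * `equal_step_lengths()` weights all steps the same:
#'   `l_t = 100 / (2 (T - 1))`.
#' * `proportional_step_lengths()` weights each step by the loss of
#'   biodiversity it represents on the master list, the decrease
#'   `L_t = S_t - S_{t+1}` in the number of taxa between consecutive levels,
#'   rescaled so the longest path is 100: `l_t = 100 L_t / (2 sum(L))`.
#'   A redundant level (zero loss) gets length 0.
#' * `unit_step_lengths()` gives every step length 1 (no standardization);
#'   distances then count steps on the tree.
#'
#' @param n_levels number of taxonomic levels `T >= 2`.
#' @param master a `taxonomy`: the master list whose per-level taxon counts
#'   define the losses.
#' @return an object of class `"step_lengths"`: list with `kind` (one of
#'   `"equal"`, `"proportional"`, `"unit"`), `lengths` (numeric vector
#'   `l_t`, `t = 1..T-1`) and `cum` (`cum[c] = 2 * sum(l_1..l_{c-1})`, the
#'   distance between OTUs first united at level `c`).
#' @examples
#' equal_step_lengths(4)                     # each step 100/6
#' m <- balanced_tree(c(9, 6, 3, 1))
#' proportional_step_lengths(m)              # losses (3, 3, 2) -> lengths
#' @name step_lengths
NULL

new_step_lengths <- function(kind, lengths) {
  if (any(lengths < 0) || all(lengths == 0)) {
    stop("step lengths must be non-negative with at least one positive")
  }
  structure(list(kind = kind,
                 lengths = as.numeric(lengths),
                 cum = c(0, 2 * cumsum(as.numeric(lengths)))),
            class = "step_lengths")
}

#' @rdname step_lengths
#' @export
equal_step_lengths <- function(n_levels) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("'n_levels' must be at least 2")
  new_step_lengths("equal", rep(100 / (2 * (n_levels - 1L)), n_levels - 1L))
}

#' @rdname step_lengths
#' @export
proportional_step_lengths <- function(master) {
  ct <- taxon_counts(master)
  loss <- -diff(ct)                    # S_t - S_{t+1}, t = 1..T-1
  # sum(loss) = S - 1 > 0 whenever S >= 2, so the rescaling is well defined
  new_step_lengths("proportional", 100 * loss / (2 * sum(loss)))
}

#' @rdname step_lengths
#' @export
unit_step_lengths <- function(n_levels) {
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("'n_levels' must be at least 2")
  new_step_lengths("unit", rep(1, n_levels - 1L))
}

#' Resolve a scheme specification against a master taxonomy
#'
#' Accepts either a ready `step_lengths` object or one of the kind strings
#' `"equal"`, `"proportional"`, `"unit"`, which is materialized from the
#' master list.  Step lengths are always derived from the master, never from
#' a pruned sample tree.
#'
#' @param scheme a `step_lengths` object or kind string.
#' @param master the master `taxonomy`.
#' @return a `step_lengths` object.
#' @export
resolve_scheme <- function(scheme, master) {
  if (inherits(scheme, "step_lengths")) {
    if (length(scheme$lengths) != length(master$levels) - 1L) {
      stop("scheme has ", length(scheme$lengths),
           " step lengths but the taxonomy has ",
           length(master$levels), " levels")
    }
    return(scheme)
  }
  scheme <- match.arg(scheme, c("proportional", "equal", "unit"))
  switch(scheme,
         equal = equal_step_lengths(length(master$levels)),
         proportional = proportional_step_lengths(master),
         unit = unit_step_lengths(length(master$levels)))
}

#' @export
print.step_lengths <- function(x, ...) {
  cat(sprintf("Step lengths (%s): %s\n", x$kind,
              paste(formatC(x$lengths, digits = 4, format = "fg"),
                    collapse = ", ")))
  invisible(x)
}

# level at which each pair of OTUs is first united: because taxa are nested,
# two OTUs that agree at level t agree at every level above, so the first
# shared level is 1 + (number of levels where they differ)
lca_levels <- function(tx) {
  cls <- tx$classification
  s <- nrow(cls)
  acc <- matrix(0L, s, s)
  for (t in seq_len(ncol(cls) - 1L)) {   # level T always agrees
    code <- match(cls[, t], unique(cls[, t]))
    acc <- acc + outer(code, code, "!=")
  }
  acc + 1L
}

#' Pairwise taxonomic distance matrix
#'
#' Computes the full symmetric matrix of taxonomic distances `omega_ij`
#' between the OTUs of a tree under a step-length scheme: `omega_ii = 0` and
#' otherwise `omega_ij = 2 (l_1 + ... + l_{c-1})` with `c` the lowest level
#' at which `i` and `j` share an ancestor.
#'
#' @param tx a `taxonomy` (master list or pruned sample tree).
#' @param scheme a `step_lengths` object or kind string (resolved against
#'   `tx`; pass a master-derived object to measure a sample tree with master
#'   step lengths).
#' @return numeric `S x S` matrix with zero diagonal and OTU dimnames.
#' @examples
#' m <- balanced_tree(c(4, 2, 1))
#' taxonomic_distance(m, "equal")
#' @export
taxonomic_distance <- function(tx, scheme = "proportional") {
  scheme <- resolve_scheme(scheme, tx)
  d <- matrix(scheme$cum[lca_levels(tx)], nrow(tx$classification))
  dimnames(d) <- list(otu_names(tx), otu_names(tx))
  d
}

#' Taxonomic distance between two OTUs
#'
#' @param tx a `taxonomy`.
#' @param i,j OTU names (or row indices).
#' @param scheme a `step_lengths` object or kind string.
#' @return the distance `omega_ij` (0 when `i == j`).
#' @export
pairwise_distance <- function(tx, i, j, scheme = "proportional") {
  scheme <- resolve_scheme(scheme, tx)
  cls <- tx$classification
  if (is.character(i) || is.character(j)) {
    miss <- setdiff(c(i, j), rownames(cls))
    if (length(miss)) stop("OTU(s) not in tree: ", paste(miss, collapse = ", "))
  }
  ri <- cls[i, ]
  rj <- cls[j, ]
  c <- match(TRUE, ri == rj)            # lowest shared level
  scheme$cum[c]
}
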