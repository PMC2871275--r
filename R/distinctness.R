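#' Average taxonomic distinctness (AvTD, Delta+)
#'
#' The mean taxonomic distance over all unordered pairs of OTUs in a tree,
#' using presence/absence only:
#' `AvTD = sum_{i<j} omega_ij / (S (S - 1) / 2)`.
#' It estimates the expected path length between a randomly selected pair of
#' OTUs, and is the core measure of how widely a sample spreads over its
#' group's taxonomy.
#'
#' @param tx a `taxonomy` with `S >= 2` OTUs.
#' @param scheme a `step_lengths` object or kind string (see
#'   [resolve_scheme()]); pass a master-derived scheme when `tx` is a pruned
#'   sample tree.
#' @return a single number, in the units of the scheme (0..100 for
#'   standardized schemes).
#' @examples
#' avtd(balanced_tree(c(9, 6, 3, 1)), unit_step_lengths(4))
#' @export
avtd <- function(tx, scheme = "proportional") {
  d <- taxonomic_distance(tx, scheme)
  mean(d[upper.tri(d)])
}

#' Variation in taxonomic distinctness (VarTD, Lambda)
#'
#' The variance of the pairwise taxonomic distances, computed as a standard
#' statistical (population) variance over the `S (S - 1) / 2` distances:
#' `VarTD = sum_{i<j} (omega_ij - AvTD)^2 / (S (S - 1) / 2)`.
#' Two trees can share an AvTD but differ in how taxa are spread across
#' intermediate levels; VarTD separates such shapes, lower values indicating
#' a more even subdivision.
#'
#' @inheritParams avtd
#' @return a single non-negative number (squared scheme units).
#' @export
vartd <- function(tx, scheme = "proportional") {
  d <- taxonomic_distance(tx, scheme)
  v <- d[upper.tri(d)]
  mean((v - mean(v))^2)
}

check_counts <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) < 2L) stop("need counts for at least 2 levels")
  if (counts[length(counts)] != 1L) {
    stop("the uppermost level must hold exactly 1 taxon")
  }
  if (any(diff(counts) > 0L)) {
    stop("taxon counts must be non-increasing from the lowest level up")
  }
  if (counts[1L] < 2L) stop("need at least 2 OTUs")
  counts
}

counts_to_taxonomy <- function(parent_of, counts, level_names) {
  # parent_of[[t]]: for each taxon at level t, index of its parent at t + 1
  T <- length(counts)
  cols <- vector("list", T)
  cols[[1L]] <- seq_len(counts[1L])
  idx <- cols[[1L]]
  cls <- matrix("", counts[1L], T)
  cls[, 1L] <- sprintf("%s_%d", level_names[1L], idx)
  for (t in seq_len(T - 1L)) {
    idx <- parent_of[[t]][idx]
    cls[, t + 1L] <- sprintf("%s_%d", level_names[t + 1L], idx)
  }
  colnames(cls) <- level_names
  taxonomy(cls, level_names)
}

default_level_names <- function(T) paste0("L", seq_len(T))

#' Extremal trees for a given set of taxon counts
#'
#' Construct the totally-imbalanced and totally-balanced taxonomic trees
#' having exactly the per-level taxon counts `S_t`.  Their AvTDs are the
#' minimum and maximum possible for those counts and anchor von Euler's
#' index of imbalance.
#'
#' `imbalanced_tree()` works bottom-up: at each level, lower taxa are
#' assigned to distinct upper taxa one by one until all upper taxa but one
#' are occupied; every remaining lower taxon is lumped into the last upper
#' taxon.
#'
#' `balanced_tree()` works top-down: the uppermost step is forced (all taxa
#' join the single root), then each level's taxa are dealt out so that
#' parent loads differ by at most one — and, because balance must hold with
#' respect to *all* upper levels, each taxon is handed to the parent whose
#' chain of ancestor loads is smallest (ties broken by index).  Extremal
#' trees need not be unique; this deterministic rule is one optimal
#' arrangement, and AvTD differences between equally balanced arrangements
#' are null or negligible.
#'
#' @param counts integer vector of taxon counts per level, lowest first;
#'   non-increasing, ending in 1, starting at `S >= 2`.
#' @param level_names optional level names.
#' @return a `taxonomy` with exactly the requested counts.
#' @examples
#' avtd(balanced_tree(c(9, 6, 3, 1)), "unit")    # 192/36
#' avtd(imbalanced_tree(c(9, 6, 3, 1)), "unit")  # 162/36
#' @export
imbalanced_tree <- function(counts, level_names = NULL) {
  counts <- check_counts(counts)
  T <- length(counts)
  if (is.null(level_names)) level_names <- default_level_names(T)
  parent_of <- vector("list", T - 1L)
  for (t in seq_len(T - 1L)) {
    n <- counts[t]
    m <- counts[t + 1L]
    parent_of[[t]] <- c(seq_len(m - 1L), rep(m, n - m + 1L))
  }
  counts_to_taxonomy(parent_of, counts, level_names)
}

#' @rdname imbalanced_tree
#' @export
balanced_tree <- function(counts, level_names = NULL) {
  counts <- check_counts(counts)
  T <- length(counts)
  if (is.null(level_names)) level_names <- default_level_names(T)
  parent_of <- vector("list", T - 1L)
  # anc[p, u]: ancestor (taxon index) of parent p at the u-th level of its
  # chain, u = 1 being p itself; one row per taxon at the level being filled
  anc <- matrix(1L, 1L, 1L)                  # level T: the root
  for (t in rev(seq_len(T - 1L))) {
    n <- counts[t]
    m <- counts[t + 1L]
    K <- ncol(anc)
    loads <- lapply(seq_len(K), function(u) integer(max(anc[, u])))
    assign <- integer(n)
    for (child in seq_len(n)) {
      best <- 1L
      for (p in seq_len(m)[-1L]) {
        # lexicographic from the top down: balance against the uppermost
        # levels takes priority over the immediate parent, so aggregated
        # OTU counts stay as even as possible at every height; ties keep
        # the lower index, making the arrangement deterministic
        for (u in rev(seq_len(K))) {
          lp <- loads[[u]][anc[p, u]]
          lb <- loads[[u]][anc[best, u]]
          if (lp < lb) { best <- p; break }
          if (lp > lb) break
        }
      }
      assign[child] <- best
      for (u in seq_len(K)) {
        a <- anc[best, u]
        loads[[u]][a] <- loads[[u]][a] + 1L
      }
    }
    parent_of[[t]] <- assign
    anc <- cbind(seq_len(n), anc[assign, , drop = FALSE])
  }
  counts_to_taxonomy(parent_of, counts, level_names)
}

#' Von Euler's index of imbalance
#'
#' `I_E = (AvTD_max - AvTD) / (AvTD_max - AvTD_min)`, where the extremes are
#' the AvTDs of the totally-balanced and totally-imbalanced trees built on
#' the observed tree's own taxon counts and measured with the same
#' step-length scheme.  `I_E` is 0 for a perfectly balanced tree, 1 for a
#' totally imbalanced one, and — unlike most imbalance indices — is defined
#' for trees with polytomies, as taxonomic trees usually are.  Values above
#' roughly 0.25 often accompany biased samples, a rule of thumb only.
#'
#' @inheritParams avtd
#' @return a number in `[0, 1]`.  When the taxon counts force a unique tree
#'   shape (`AvTD_max == AvTD_min`) the index is returned as 0 with a
#'   warning, the tree being simultaneously maximally balanced and
#'   imbalanced.
#' @section Anchor tightness: the imbalanced anchor is exact (no tree with
#'   the same counts can have a lower AvTD), while the balanced anchor is
#'   the canonical deterministic construction: for a few degenerate count
#'   vectors (adjacent small counts, e.g. 12 OTUs over counts 12, 3, 2, 1)
#'   a particular tree can exceed its AvTD by a negligible margin (about
#'   2% at most in randomized checks).  The ratio is therefore truncated
#'   into `[0, 1]`.
#' @examples
#' euler_imbalance(balanced_tree(c(9, 6, 3, 1)), "unit")  # 0
#' @export
euler_imbalance <- function(tx, scheme = "proportional") {
  scheme <- resolve_scheme(scheme, tx)
  ext <- extremal_avtd(taxon_counts(tx), scheme)
  if (ext[["max"]] - ext[["min"]] <= .Machine$double.eps * 100) {
    warning("taxon counts admit a single tree shape; imbalance set to 0")
    return(0)
  }
  ie <- (ext[["max"]] - avtd(tx, scheme)) / (ext[["max"]] - ext[["min"]])
  min(1, max(0, unname(ie)))
}

extremal_avtd <- function(counts, scheme) {
  c(max = avtd(balanced_tree(counts), scheme),
    min = avtd(imbalanced_tree(counts), scheme))
}

#' Taxonomic distinctness summary of one tree
#'
#' Computes AvTD, VarTD, von Euler's imbalance index and the extremal AvTDs
#' for a sample tree in one pass, under a common step-length scheme.
#'
#' @param tx a `taxonomy` (typically a sample pruned from a master list).
#' @param scheme a `step_lengths` object or kind string; pass the
#'   master-derived scheme when assessing a sample.
#' @return an object of class `"distinctness"`: list with `s` (number of
#'   OTUs), `avtd`, `vartd`, `ie`, `avtd_max`, `avtd_min`, `scheme_kind`,
#'   and `flag_imbalanced` (`TRUE` when `ie > 0.25`, the rule-of-thumb
#'   screen for biased samples).
#' @examples
#' m <- balanced_tree(c(16, 8, 4, 1))
#' distinctness(m, "equal")
#' @export
distinctness <- function(tx, scheme = "proportional") {
  scheme <- resolve_scheme(scheme, tx)
  d <- taxonomic_distance(tx, scheme)
  v <- d[upper.tri(d)]
  a <- mean(v)
  ext <- extremal_avtd(taxon_counts(tx), scheme)
  ie <- if (ext[["max"]] - ext[["min"]] <= .Machine$double.eps * 100) {
    0
  } else {
    # truncated into [0, 1]: see the anchor-tightness note in
    # ?euler_imbalance
    min(1, max(0, unname((ext[["max"]] - a) / (ext[["max"]] - ext[["min"]]))))
  }
  structure(list(s = nrow(tx$classification),
                 avtd = a,
                 vartd = mean((v - a)^2),
                 ie = ie,
                 avtd_max = unname(ext[["max"]]),
                 avtd_min = unname(ext[["min"]]),
                 scheme_kind = scheme$kind,
                 flag_imbalanced = ie > 0.25),
            class = "distinctness")
}

#' @export
print.distinctness <- function(x, ...) {
  cat(sprintf("Taxonomic distinctness (%s scheme), S = %d\n",
              x$scheme_kind, x$s))
  cat(sprintf("  AvTD  = %.4f   [min %.4f, max %.4f]\n",
              x$avtd, x$avtd_min, x$avtd_max))
  cat(sprintf("  VarTD = %.4f\n", x$vartd))
  cat(sprintf("  I_E   = %.4f%s\n", x$ie,
              if (x$flag_imbalanced) "  (> 0.25: possible biased sample)"
              else ""))
  invisible(x)
}

#' @export
as.data.frame.distinctness <- function(x, ...) {
  data.frame(s = x$s, avtd = x$avtd, vartd = x$vartd, ie = x$ie,
             avtd_max = x$avtd_max, avtd_min = x$avtd_min,
             scheme_kind = x$scheme_kind)
}
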