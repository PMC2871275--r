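#' Generate a synthetic taxonomy with given per-level taxon counts
#'
#' Builds a random Linnean hierarchy with exactly the requested number of
#' taxa at each level, for use as a test master list when no real taxonomy
#' is at hand.  Going down from the root, each level's taxa are attached to
#' parents either uniformly at random subject to every parent keeping at
#' least one child (a random surjection: one child per parent first, the
#' surplus placed uniformly), or deterministically via the balanced or
#' imbalanced extremal constructions.
#'
#' Synthetic taxonomies emulate the *structure* of real master lists — a
#' strict hierarchy with polytomies and uneven taxon sizes — but not the
#' evolutionary correlations of real classifications, where closely related
#' groups share revision history.
#'
#' @param counts integer vector of taxon counts per level, lowest first;
#'   non-increasing, ending in 1.
#' @param method `"random"` (default), `"balanced"` or `"imbalanced"`.
#' @param level_names optional level names.
#' @param seed optional integer seed (used by `"random"` only).
#' @return a `taxonomy` with `taxon_counts()` equal to `counts`.
#' @examples
#' m <- synthetic_taxonomy(c(50, 18, 5, 1), seed = 42)
#' taxon_counts(m)
#' @export
synthetic_taxonomy <- function(counts, method = c("random", "balanced",
                                                  "imbalanced"),
                               level_names = NULL, seed = NULL) {
  method <- match.arg(method)
  if (method == "balanced") return(balanced_tree(counts, level_names))
  if (method == "imbalanced") return(imbalanced_tree(counts, level_names))
  counts <- check_counts(counts)
  T <- length(counts)
  if (is.null(level_names)) level_names <- default_level_names(T)
  with_seed(seed, {
    parent_of <- vector("list", T - 1L)
    for (t in seq_len(T - 1L)) {
      n <- counts[t]
      m <- counts[t + 1L]
      assign <- integer(n)
      occupied <- sample.int(n, m)          # one child per parent: no empties
      assign[occupied] <- sample.int(m, m)
      rest <- setdiff(seq_len(n), occupied)
      if (length(rest)) {
        assign[rest] <- sample.int(m, length(rest), replace = TRUE)
      }
      parent_of[[t]] <- assign
    }
    counts_to_taxonomy(parent_of, counts, level_names)
  })
}
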