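# Helpers over the flat classification table ------------------------------

level_index <- function(tx, level) {
  if (is.character(level)) {
    i <- match(level, tx$levels)
    if (is.na(i)) {
      stop("unknown level '", level, "'; valid levels: ",
           paste(tx$levels, collapse = ", "))
    }
    return(i)
  }
  i <- as.integer(level)
  if (i < 1L || i > length(tx$levels)) {
    stop("level index out of range 1..", length(tx$levels))
  }
  i
}

# taxa at level t whose parent at t + 1 holds >= 2 taxa of level t
taxa_with_siblings <- function(cls, t) {
  pairs <- unique(cls[, c(t, t + 1L), drop = FALSE])
  sib <- table(pairs[, 2L])
  pairs[sib[pairs[, 2L]] >= 2L, 1L]
}

unique_name <- function(base, taken) {
  nm <- base
  i <- 1L
  while (nm %in% taken) {
    i <- i + 1L
    nm <- paste0(base, ".", i)
  }
  nm
}

#' Taxonomic revision moves
#'
#' The three elementary moves taxonomists make when revising a
#' classification, applied at a chosen level `t` with a random draw.  In all
#' moves downstream relationships are maintained: if genus *a* containing
#' species *x* and *y* is transferred from family *A* to family *B*, *x* and
#' *y* still belong to *a* within *B*.
#'
#' * `move_transfer()` (`t` in `1..T-1`): a random taxon *a* at level `t`
#'   whose parent *A* contains other taxa besides *a* is reparented under a
#'   random taxon *B != A* at level `t + 1`.  All per-level taxon counts are
#'   conserved.
#' * `move_split()` (`t` in `2..T-1`): a random taxon *a* at level `t` with
#'   at least two children is split in place into two new non-empty taxa
#'   (`a_split1`, `a_split2`) by a uniform random bipartition of its
#'   children; the count at level `t` increases by one.
#' * `move_merge()` (`t` in `2..T-1`): a random taxon *a* whose parent *A*
#'   holds further taxa is merged with a random sibling *b* drawn within
#'   *A*, into a new taxon `a+b_merged` in the same position; the count at
#'   level `t` decreases by one.
#'
#' Draws are uniform over the taxa for which the move is legal (equivalent
#' in law to the rejection-sampling formulation, redrawing on an illegal
#' pick); if no legal pick exists the move errors rather than looping.
#'
#' @param tx a `taxonomy`.
#' @param t level index or name at which the move operates.
#' @param seed optional integer seed.
#' @return the revised `taxonomy`.
#' @examples
#' m <- balanced_tree(c(9, 6, 3, 1))
#' taxon_counts(move_split(m, 2, seed = 1))
#' @name moves
NULL

#' @rdname moves
#' @export
move_transfer <- function(tx, t, seed = NULL) {
  t <- level_index(tx, t)
  T <- length(tx$levels)
  if (t >= T) stop("transfer operates at levels 1..T-1")
  cls <- tx$classification
  parents <- unique(cls[, t + 1L])
  if (length(parents) < 2L) {
    stop("no legal transfer: only one taxon at level ", t + 1L)
  }
  movable <- taxa_with_siblings(cls, t)
  if (!length(movable)) {
    stop("no legal transfer at level ", t,
         ": every parent holds a single taxon")
  }
  with_seed(seed, {
    a <- movable[sample.int(length(movable), 1L)]
    rows_a <- which(cls[, t] == a)
    A <- cls[rows_a[1L], t + 1L]
    candidates <- setdiff(parents, A)
    B <- candidates[sample.int(length(candidates), 1L)]
    # adopt B's full ancestor chain
    row_B <- which(cls[, t + 1L] == B)[1L]
    cls[rows_a, (t + 1L):T] <- rep(cls[row_B, (t + 1L):T],
                                   each = length(rows_a))
    taxonomy(cls, tx$levels)
  })
}

#' @rdname moves
#' @export
move_split <- function(tx, t, seed = NULL) {
  t <- level_index(tx, t)
  T <- length(tx$levels)
  if (t < 2L || t >= T) stop("split operates at levels 2..T-1")
  cls <- tx$classification
  kids <- unique(cls[, c(t - 1L, t), drop = FALSE])
  nkids <- table(kids[, 2L])
  splittable <- names(nkids)[nkids >= 2L]
  if (!length(splittable)) {
    stop("no splittable taxon at level ", t, ": all have a single child")
  }
  with_seed(seed, {
    a <- splittable[sample.int(length(splittable), 1L)]
    children <- kids[kids[, 2L] == a, 1L]
    # uniform random bipartition into two non-empty labeled subsets
    repeat {
      side <- sample(c(TRUE, FALSE), length(children), replace = TRUE)
      if (any(side) && !all(side)) break
    }
    taken <- unique(cls[, t])
    n1 <- unique_name(paste0(a, "_split1"), taken)
    n2 <- unique_name(paste0(a, "_split2"), c(taken, n1))
    in1 <- cls[, t] == a & cls[, t - 1L] %in% children[side]
    in2 <- cls[, t] == a & !in1
    cls[in1, t] <- n1
    cls[in2, t] <- n2
    taxonomy(cls, tx$levels)
  })
}

#' @rdname moves
#' @export
move_merge <- function(tx, t, seed = NULL) {
  t <- level_index(tx, t)
  T <- length(tx$levels)
  if (t < 2L || t >= T) stop("merge operates at levels 2..T-1")
  cls <- tx$classification
  mergeable <- taxa_with_siblings(cls, t)
  if (!length(mergeable)) {
    stop("no mergeable pair at level ", t,
         ": every parent holds a single taxon")
  }
  with_seed(seed, {
    a <- mergeable[sample.int(length(mergeable), 1L)]
    A <- cls[which(cls[, t] == a)[1L], t + 1L]
    siblings <- setdiff(unique(cls[cls[, t + 1L] == A, t]), a)
    b <- siblings[sample.int(length(siblings), 1L)]
    nm <- unique_name(paste0(a, "+", b, "_merged"), unique(cls[, t]))
    cls[cls[, t] %in% c(a, b), t] <- nm
    taxonomy(cls, tx$levels)
  })
}

#' Specify a set of shuffling moves
#'
#' A shuffle specification lists how many times each move kind is applied at
#' which level when producing one "reviewed" master list, mimicking the
#' intensity of taxonomic revision the user judges plausible for their
#' group.  No formal criterion fixes these counts; they are an
#' expertise-driven choice.
#'
#' @param moves a data frame with columns `move` (`"split"`, `"merge"`,
#'   `"transfer"`), `level` (index or name) and `times` (non-negative
#'   integer); rows are applied in order.  Alternatively build one from the
#'   shorthand arguments.
#' @param splits,merges,transfers shorthand counts, all applied at `level`
#'   in the order split, merge, transfer.
#' @param level level (index or name) for the shorthand form.
#' @return an object of class `"shuffle_spec"`.
#' @examples
#' shuffle_spec(splits = 2, merges = 1, transfers = 2, level = "family")
#' @export
shuffle_spec <- function(moves = NULL, splits = 0, merges = 0, transfers = 0,
                         level = NULL) {
  if (is.null(moves)) {
    if (is.null(level)) stop("supply 'level' with the shorthand counts")
    moves <- data.frame(move = c("split", "merge", "transfer"),
                        level = level,
                        times = c(splits, merges, transfers),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(moves),
            all(c("move", "level", "times") %in% names(moves)))
  moves$move <- as.character(moves$move)
  bad <- setdiff(moves$move, c("split", "merge", "transfer"))
  if (length(bad)) {
    stop("unknown move kind(s): ", paste(bad, collapse = ", "),
         " (valid: split, merge, transfer)")
  }
  moves$times <- as.integer(moves$times)
  if (any(moves$times < 0L)) stop("'times' must be non-negative")
  structure(list(moves = moves), class = "shuffle_spec")
}

#' @export
print.shuffle_spec <- function(x, ...) {
  cat("Shuffle specification:\n")
  print(x$moves, row.names = FALSE)
  invisible(x)
}

apply_shuffle_spec <- function(master, spec) {
  tx <- master
  for (r in seq_len(nrow(spec$moves))) {
    mv <- spec$moves$move[r]
    lv <- spec$moves$level[r]
    for (i in seq_len(spec$moves$times[r])) {
      tx <- switch(mv,
                   split = move_split(tx, lv),
                   merge = move_merge(tx, lv),
                   transfer = move_transfer(tx, lv))
    }
  }
  tx
}

#' Generate shuffled ("reviewed") master lists
#'
#' Produces `n_lists` revised versions of the master list, each obtained by
#' applying the specification's moves, in order, to a fresh copy of the
#' master.  With a fixed seed the whole sequence is reproducible.
#'
#' @param master a `taxonomy`.
#' @param spec a [shuffle_spec()].
#' @param n_lists number of shuffled lists.
#' @param seed optional integer seed.
#' @return a list of `taxonomy` objects of length `n_lists`.
#' @export
shuffled_master_lists <- function(master, spec, n_lists, seed = NULL) {
  stopifnot(inherits(spec, "shuffle_spec"))
  with_seed(seed, lapply(seq_len(n_lists),
                         function(i) apply_shuffle_spec(master, spec)))
}

#' Stability of funnel statistics under simulated taxonomic revision
#'
#' Runs the full funnel analysis on every shuffled master list (recomputing
#' proportional step lengths per list, since revision changes taxon counts)
#' and aggregates the six funnel series across lists: for the lower AvTD 95%
#' limit, mean AvTD, mean VarTD and upper VarTD 95% limit, two-tailed
#' 2.5%/97.5% confidence bands across lists at each dimension `s`; for the
#' maximum AvTD and minimum VarTD, the extreme entry across lists.  Narrow
#' bands mean the representativeness verdict is robust to plausible
#' taxonomic revision.
#'
#' @param master a `taxonomy`.
#' @param spec a [shuffle_spec()].
#' @param n_lists number of shuffled master lists (1,000 gives smooth bands;
#'   smaller values are fine for exploration).
#' @param s_range subsample dimensions.
#' @param k replicates per dimension per list.
#' @param scheme scheme kind string, or a `step_lengths` object to hold the
#'   weights fixed across lists.
#' @param seed optional integer seed.
#' @param band two-tailed band level (default 0.95, i.e. 2.5%/97.5%).
#' @details Each shuffled list is generated under its own derived seed, and
#'   every per-list funnel analysis reuses one shared funnel seed (common
#'   random numbers), so differences between lists reflect the taxonomic
#'   perturbation, not resampling noise; with a zero-move specification the
#'   bands collapse exactly onto the single master's funnel lines.
#' @return a data frame of class `"shuffle_bands"`: one row per `s` with
#'   columns `<stat>_lo`/`<stat>_hi` for the four banded statistics plus
#'   `max_avtd` and `min_vartd`; attributes `n_lists`, `k`, `seed`,
#'   `funnel_seed`, `scheme_kind`.
#' @export
shuffling_analysis <- function(master, spec, n_lists, s_range, k = 100,
                               scheme = "proportional", seed = NULL,
                               band = 0.95) {
  seeds <- with_seed(seed,
                     sample.int(.Machine$integer.max, n_lists + 1L))
  funnel_seed <- seeds[n_lists + 1L]
  {
    funnels <- lapply(seq_len(n_lists), function(i) {
      tx <- with_seed(seeds[i], apply_shuffle_spec(master, spec))
      funnel_analysis(tx, s_range = s_range, k = k, scheme = scheme,
                      seed = funnel_seed)
    })
    lo <- (1 - band) / 2
    hi <- 1 - lo
    s_range <- sort(unique(as.integer(s_range)))
    banded <- c("lower95_avtd", "mean_avtd", "mean_vartd", "upper95_vartd")
    rows <- lapply(seq_along(s_range), function(si) {
      row <- list(s = s_range[si])
      for (stat in banded) {
        vals <- vapply(funnels, function(f) f[[stat]][si], numeric(1))
        row[[paste0(stat, "_lo")]] <- attained_quantile(vals, lo)
        row[[paste0(stat, "_hi")]] <- attained_quantile(vals, hi)
      }
      row$max_avtd <- max(vapply(funnels, function(f) f$max_avtd[si],
                                 numeric(1)))
      row$min_vartd <- min(vapply(funnels, function(f) f$min_vartd[si],
                                  numeric(1)))
      as.data.frame(row)
    })
    structure(do.call(rbind, rows),
              class = c("shuffle_bands", "data.frame"),
              n_lists = as.integer(n_lists), k = as.integer(k),
              seed = seed, funnel_seed = funnel_seed,
              scheme_kind = if (inherits(scheme, "step_lengths"))
                scheme$kind else scheme)
  }
}
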