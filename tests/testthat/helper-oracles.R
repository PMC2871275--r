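# The 9-OTU / 4-level worked-example tree: genera {1,2,3},{4},{5},{6,7},
# {8},{9}; families {sp1..sp5},{sp6..sp8},{sp9}; one order.
worked_example_tree <- function() {
  taxonomy(data.frame(
    species = paste0("sp", 1:9),
    genus   = c("G1", "G1", "G1", "G2", "G3", "G4", "G4", "G5", "G6"),
    family  = c("F1", "F1", "F1", "F1", "F1", "F2", "F2", "F2", "F3"),
    order   = "O1"
  ))
}

# Naive all-pairs double loop straight off the classification rows: for each
# pair scan levels for the first shared ancestor.  Independent of the
# vectorized matrix path used by the package.
naive_distinctness <- function(tx, scheme) {
  cls <- tx$classification
  s <- nrow(cls)
  lens <- scheme$lengths
  d <- c()
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) {
      c_lvl <- 1L
      while (cls[i, c_lvl] != cls[j, c_lvl]) c_lvl <- c_lvl + 1L
      d <- c(d, 2 * sum(lens[seq_len(c_lvl - 1L)]))
    }
  }
  list(avtd = mean(d), vartd = mean((d - mean(d))^2), distances = d)
}

# Shortest paths on the explicit node-edge graph of the taxonomy, via
# igraph: nodes are (level, taxon) pairs, edges join each taxon to its
# parent with weight l_t.
graph_distances <- function(tx, scheme) {
  cls <- tx$classification
  T <- ncol(cls)
  node <- function(t, nm) paste0("L", t, ":", nm)
  edges <- character(0)
  weights <- numeric(0)
  for (t in seq_len(T - 1L)) {
    pairs <- unique(cls[, c(t, t + 1L), drop = FALSE])
    for (r in seq_len(nrow(pairs))) {
      edges <- c(edges, node(t, pairs[r, 1L]), node(t + 1L, pairs[r, 2L]))
      weights <- c(weights, scheme$lengths[t])
    }
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  tips <- node(1L, cls[, 1L])
  d <- igraph::distances(g, v = tips, to = tips, weights = weights)
  dimnames(d) <- list(unname(cls[, 1L]), unname(cls[, 1L]))
  d
}

random_counts <- function(max_s = 30, n_levels = NULL) {
  T <- if (is.null(n_levels)) sample(3:5, 1) else n_levels
  s <- sample(4:max_s, 1)
  counts <- c(s, integer(T - 2), 1)
  for (t in 2:(T - 1)) {
    counts[t] <- sample(seq(counts[T], counts[t - 1]), 1)
  }
  sort(counts, decreasing = TRUE)
}
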