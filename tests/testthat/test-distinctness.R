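test_that("AvTD and VarTD reproduce the worked example", {
  wex <- worked_example_tree()
  expect_equal(avtd(wex, "unit"), 182 / 36, tolerance = 1e-12)
  expect_equal(round(avtd(wex, "unit"), 4), 5.0556)
  expect_equal(vartd(wex, "unit"), 988 / 36 - (182 / 36)^2,
               tolerance = 1e-12)
  # equal standardization is a uniform rescaling of unit steps
  expect_equal(avtd(wex, "equal"), 182 / 36 * 100 / 6, tolerance = 1e-12)
  expect_equal(vartd(wex, "equal"), (988 / 36 - (182 / 36)^2) * (100 / 6)^2,
               tolerance = 1e-9)
})

test_that("degenerate tree shapes give the expected statistics", {
  # every OTU its own lineage: all pairs at the maximum distance
  star <- taxonomy(data.frame(sp = paste0("s", 1:5),
                              genus = paste0("g", 1:5),
                              family = paste0("f", 1:5), top = "T"))
  expect_equal(avtd(star, "equal"), 100)
  expect_equal(avtd(star, "proportional"), 100)
  expect_equal(vartd(star, "equal"), 0)
  # a single pair has zero variance
  expect_equal(vartd(balanced_tree(c(2, 1)), "unit"), 0)
})

test_that("matrix-path AvTD/VarTD match the naive double loop", {
  for (seed in 1:30) {
    tx <- synthetic_taxonomy(random_counts(30), seed = seed)
    for (kind in c("unit", "proportional")) {
      scheme <- resolve_scheme(kind, tx)
      oracle <- naive_distinctness(tx, scheme)
      expect_equal(avtd(tx, scheme), oracle$avtd, tolerance = 1e-9)
      expect_equal(vartd(tx, scheme), oracle$vartd, tolerance = 1e-9)
    }
  }
})

test_that("AvTD and VarTD agree with vegan's taxondive on equal steps", {
  skip_if_not_installed("vegan")
  # strictly decreasing counts: vegan::taxa2dist silently drops levels
  # whose richness is 1 or S, where the two parameterizations differ
  cases <- list(c(20, 8, 3, 1), c(15, 10, 4, 1), c(12, 6, 2, 1),
                c(25, 9, 5, 1), c(18, 7, 3, 1))
  for (seed in seq_along(cases)) {
    tx <- synthetic_taxonomy(cases[[seed]], seed = seed)
    cls <- as.data.frame(tx$classification[, -1, drop = FALSE])
    rownames(cls) <- otu_names(tx)
    d <- vegan::taxa2dist(cls, varstep = FALSE)
    comm <- matrix(1, 1, nrow(cls), dimnames = list(NULL, rownames(cls)))
    td <- vegan::taxondive(comm, d)
    expect_equal(avtd(tx, "equal"), unname(td$Dplus), tolerance = 1e-9)
    expect_equal(vartd(tx, "equal"), unname(td$Lambda), tolerance = 1e-9)
  }
})

test_that("the imbalanced builder lumps the surplus into the last taxon", {
  it <- imbalanced_tree(c(9, 6, 3, 1))
  expect_equal(unname(taxon_counts(it)), c(9, 6, 3, 1))
  genus_sizes <- sort(unname(table(it$classification[, 2])))
  expect_equal(as.vector(genus_sizes), c(1, 1, 1, 1, 1, 4))
  fam_genera <- table(unique(it$classification[, 2:3])[, 2])
  expect_equal(sort(as.vector(fam_genera)), c(1, 1, 4))
  expect_equal(avtd(it, "unit"), 162 / 36, tolerance = 1e-12)

  # forced shapes
  expect_equal(unname(taxon_counts(imbalanced_tree(c(5, 1)))), c(5, 1))
  one2one <- imbalanced_tree(c(4, 4, 2, 1))
  expect_equal(unname(taxon_counts(one2one)), c(4, 4, 2, 1))
  expect_error(imbalanced_tree(c(3, 4, 1)), "non-increasing")
})

test_that("the balanced builder balances against all upper levels", {
  bt <- balanced_tree(c(9, 6, 3, 1))
  expect_equal(unname(taxon_counts(bt)), c(9, 6, 3, 1))
  # 2 genera per family; per family one genus of 2 species and one of 1
  fam_of_genus <- unique(bt$classification[, 2:3])
  expect_equal(as.vector(sort(table(fam_of_genus[, 2]))), c(2, 2, 2))
  genus_sizes <- table(bt$classification[, 2])
  expect_equal(sort(as.vector(genus_sizes)), c(1, 1, 1, 2, 2, 2))
  otus_per_family <- table(bt$classification[, 3])
  expect_equal(as.vector(otus_per_family), c(3, 3, 3))
  expect_equal(avtd(bt, "unit"), 192 / 36, tolerance = 1e-12)

  expect_equal(sort(as.vector(table(balanced_tree(c(4, 2, 1))$classification[, 2]))),
               c(2, 2))
  # each OTU its own genus when counts force it
  expect_equal(unname(taxon_counts(balanced_tree(c(5, 5, 1)))), c(5, 5, 1))
})

test_that("extremal trees bracket every random tree with the same counts", {
  # the imbalanced anchor is exact; the balanced anchor is the canonical
  # construction, which a degenerate tree can beat only by the negligible
  # margin tolerated between equally-balanced arrangements (see
  # ?euler_imbalance)
  for (seed in 1:8) {
    counts <- random_counts(12, n_levels = 4)
    scheme <- resolve_scheme("equal", balanced_tree(counts))
    hi <- avtd(balanced_tree(counts), scheme)
    lo <- avtd(imbalanced_tree(counts), scheme)
    for (r in 1:40) {
      a <- avtd(synthetic_taxonomy(counts, seed = seed * 1000 + r), scheme)
      expect_lte(a, hi * 1.03)
      expect_gte(a, lo - 1e-9)
    }
  }
})

test_that("degenerate counts keep I_E in range despite a loose max anchor", {
  # counts (12, 3, 2, 1): a tree with genus sizes (5, 4, 3) exceeds the
  # balanced construction's AvTD slightly; the index must still be in
  # [0, 1] and the lower anchor must still hold
  counts <- c(12, 3, 2, 1)
  hi <- avtd(balanced_tree(counts), "unit")
  lo <- avtd(imbalanced_tree(counts), "unit")
  seen_excess <- FALSE
  for (r in 1:200) {
    tx <- synthetic_taxonomy(counts, seed = r)
    di <- distinctness(tx, "unit")
    if (di$avtd > hi) seen_excess <- TRUE
    expect_gte(di$avtd, lo - 1e-9)
    expect_lte(di$avtd, hi * 1.03)
    expect_gte(di$ie, 0)
    expect_lte(di$ie, 1)
  }
  expect_true(seen_excess)
})

test_that("von Euler's index behaves across the balance range", {
  wex <- worked_example_tree()
  expect_equal(euler_imbalance(wex, "unit"), 1 / 3, tolerance = 1e-12)
  counts <- unname(taxon_counts(wex))
  expect_equal(euler_imbalance(balanced_tree(counts), "unit"), 0)
  expect_equal(euler_imbalance(imbalanced_tree(counts), "unit"), 1)
  # invariant under uniform rescaling of all step lengths
  expect_equal(euler_imbalance(wex, "unit"),
               euler_imbalance(wex, "equal"), tolerance = 1e-12)
  # counts admitting a single shape: warning and 0
  expect_warning(ie <- euler_imbalance(balanced_tree(c(3, 1)), "unit"),
                 "single tree shape")
  expect_equal(ie, 0)
})

test_that("the distinctness summary is coherent and flags imbalance", {
  for (seed in 1:10) {
    tx <- synthetic_taxonomy(random_counts(20), seed = seed)
    di <- distinctness(tx, "proportional")
    expect_gte(di$avtd, di$avtd_min - 1e-9)
    expect_lte(di$avtd, di$avtd_max * 1.03)
    expect_gte(di$ie, 0)
    expect_lte(di$ie, 1)
    expect_gte(di$vartd, 0)
    expect_equal(di$flag_imbalanced, di$ie > 0.25)
  }
  df <- as.data.frame(distinctness(worked_example_tree(), "unit"))
  expect_equal(df$avtd, 182 / 36)
  expect_equal(df$scheme_kind, "unit")
})
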