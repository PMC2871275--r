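test_that("transfer conserves every per-level taxon count", {
  wex <- worked_example_tree()
  for (seed in 1:10) {
    out <- move_transfer(wex, 2, seed = seed)
    expect_equal(taxon_counts(out), taxon_counts(wex))
    expect_setequal(otu_names(out), otu_names(wex))
  }
  # transferring a genus keeps its species inside it
  moved <- move_transfer(wex, 2, seed = 1)
  g_of <- function(tx, sp) tx$classification[sp, "genus"]
  expect_equal(g_of(moved, "sp6"), g_of(wex, "sp6"))
  expect_equal(g_of(moved, "sp7"), g_of(wex, "sp7"))

  # a single taxon at t + 1 leaves no legal transfer
  one_parent <- taxonomy(data.frame(sp = c("a", "b"), g = c("ga", "gb"),
                                    top = "T"))
  expect_error(move_transfer(one_parent, 2), "only one taxon")
})

test_that("split raises the level count by one, conserving OTUs", {
  wex <- worked_example_tree()
  out <- move_split(wex, 2, seed = 3)
  expect_equal(unname(taxon_counts(out)), c(9, 7, 3, 1))
  expect_setequal(otu_names(out), otu_names(wex))

  # a 2-child taxon splits into two singletons
  small <- taxonomy(data.frame(sp = c("a", "b"), g = "G", f = "F",
                               top = "T"))
  sp <- move_split(small, 2, seed = 1)
  expect_equal(unname(taxon_counts(sp)), c(2, 2, 1, 1))

  # splitting exhausts once every taxon holds a single child
  tx <- wex
  for (i in 1:3) tx <- move_split(tx, 2, seed = i)   # 6 -> 9 genera
  expect_equal(unname(taxon_counts(tx))[2], 9)
  expect_error(move_split(tx, 2), "no splittable")
  expect_error(move_split(wex, 1), "levels 2..T-1")
  expect_error(move_split(wex, 4), "levels 2..T-1")
})

test_that("merge lowers the level count by one, within one parent", {
  wex <- worked_example_tree()
  out <- move_merge(wex, 2, seed = 2)
  expect_equal(unname(taxon_counts(out)), c(9, 5, 3, 1))
  expect_setequal(otu_names(out), otu_names(wex))
  # merged partners always shared their family
  for (seed in 1:8) {
    m <- move_merge(wex, 2, seed = seed)
    merged <- setdiff(unique(m$classification[, 2]),
                      unique(wex$classification[, 2]))
    fams <- unique(m$classification[m$classification[, 2] == merged, 3])
    expect_length(fams, 1)
  }
  # all parents singleton: no mergeable pair
  singl <- taxonomy(data.frame(sp = c("a", "b"), g = c("ga", "gb"),
                               f = c("fa", "fb"), top = "T"))
  expect_error(move_merge(singl, 2), "no mergeable")

  # merge then split restores the count (not necessarily the partition)
  ms <- move_split(move_merge(wex, 2, seed = 5), 2, seed = 5)
  expect_equal(unname(taxon_counts(ms))[2], 6)
})

test_that("every legal move yields a valid taxonomy", {
  m <- synthetic_taxonomy(c(25, 10, 4, 1), seed = 12)
  for (seed in 1:6) {
    expect_silent(validate_taxonomy(move_transfer(m, 1, seed = seed)))
    expect_silent(validate_taxonomy(move_transfer(m, 2, seed = seed)))
    expect_silent(validate_taxonomy(move_split(m, 2, seed = seed)))
    expect_silent(validate_taxonomy(move_merge(m, 3, seed = seed)))
  }
})

test_that("shuffled list generation follows its move specification and seed", {
  m <- synthetic_taxonomy(c(40, 15, 6, 1), seed = 20)

  none <- shuffle_spec(level = 2)           # zero moves
  lists <- shuffled_master_lists(m, none, 4, seed = 1)
  for (l in lists) expect_identical(l$classification, m$classification)

  # transfers only: every output keeps the master's counts
  tr <- shuffle_spec(transfers = 5, level = 1)
  for (l in shuffled_master_lists(m, tr, 5, seed = 2)) {
    expect_equal(taxon_counts(l), taxon_counts(m))
  }

  # splits and merges shift the level count by their difference
  sm <- shuffle_spec(splits = 3, merges = 1, transfers = 2, level = 2)
  for (l in shuffled_master_lists(m, sm, 5, seed = 3)) {
    expect_equal(unname(taxon_counts(l))[2], 15 + 3 - 1)
    expect_equal(unname(taxon_counts(l))[c(1, 3, 4)], c(40, 6, 1))
  }

  expect_identical(
    lapply(shuffled_master_lists(m, sm, 3, seed = 9), `[[`, "classification"),
    lapply(shuffled_master_lists(m, sm, 3, seed = 9), `[[`, "classification"))

  expect_error(shuffle_spec(moves = data.frame(move = "explode", level = 2,
                                               times = 1)),
               "unknown move")
})

test_that("shuffle bands collapse without perturbation, stay ordered with it", {
  m <- synthetic_taxonomy(c(40, 15, 6, 1), seed = 30)
  s_range <- c(5, 10, 20)

  none <- shuffle_spec(level = 2)
  bands <- shuffling_analysis(m, none, n_lists = 5, s_range = s_range,
                              k = 20, seed = 44)
  ft <- funnel_analysis(m, s_range = s_range, k = 20,
                        seed = attr(bands, "funnel_seed"))
  for (stat in c("lower95_avtd", "mean_avtd", "mean_vartd",
                 "upper95_vartd")) {
    expect_equal(bands[[paste0(stat, "_lo")]], ft[[stat]])
    expect_equal(bands[[paste0(stat, "_hi")]], ft[[stat]])
  }
  expect_equal(bands$max_avtd, ft$max_avtd)
  expect_equal(bands$min_vartd, ft$min_vartd)

  # single list: zero-width bands even with real moves
  one <- shuffling_analysis(m, shuffle_spec(splits = 1, merges = 1,
                                            transfers = 2, level = 2),
                            n_lists = 1, s_range = s_range, k = 10,
                            seed = 5)
  expect_equal(one$mean_avtd_lo, one$mean_avtd_hi)

  # perturbed bands are ordered and reproducible
  sp <- shuffle_spec(splits = 2, merges = 1, transfers = 3, level = 2)
  b1 <- shuffling_analysis(m, sp, n_lists = 8, s_range = s_range,
                           k = 15, seed = 77)
  b2 <- shuffling_analysis(m, sp, n_lists = 8, s_range = s_range,
                           k = 15, seed = 77)
  expect_identical(b1, b2)
  for (stat in c("lower95_avtd", "mean_avtd", "mean_vartd",
                 "upper95_vartd")) {
    expect_true(all(b1[[paste0(stat, "_lo")]] <=
                      b1[[paste0(stat, "_hi")]] + 1e-12))
  }
})

test_that("heavy low-level shuffling depresses AvTD on a sensitive taxonomy", {
  # a balanced tree is maximally distinct; random transfers of OTUs between
  # genera can only concentrate lineages, so the mean AvTD across shuffled
  # lists falls below the unshuffled mean
  m <- balanced_tree(c(36, 12, 4, 1))
  sp <- shuffle_spec(transfers = 20, level = 1)
  bands <- shuffling_analysis(m, sp, n_lists = 10, s_range = c(10, 18),
                              k = 20, scheme = "equal", seed = 101)
  ft <- funnel_analysis(m, s_range = c(10, 18), k = 20, scheme = "equal",
                        seed = attr(bands, "funnel_seed"))
  expect_true(all(bands$mean_avtd_lo < ft$mean_avtd))
})
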