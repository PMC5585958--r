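test_that("universe assigns bits in sorted gene order and filters annotation-only genes", {
  ints <- interactions_from_lines(c("miR-a,g3", "miR-a,g1", "miR-b,g2"))
  anns <- annotations_from_lines(c("g1,C1,one", "g4,C1,one"))

  u <- build_universe(ints, anns)
  expect_equal(u$size, 3L)
  expect_equal(u$gene_at, c("g1", "g2", "g3"))
  expect_equal(unname(u$index_of[c("g1", "g2", "g3")]), 0:2)
  expect_false("g4" %in% u$gene_at)

  u2 <- build_universe(ints, anns, include_annotation_only_genes = TRUE)
  expect_equal(u2$size, 4L)
  expect_true("g4" %in% u2$gene_at)

  empty <- ints
  empty$entries <- ints$entries[0, ]
  expect_error(build_universe(empty), class = "mirset_input_error")
})

test_that("universe positions equal rank in sorted id order on generated data", {
  sc <- small_scenario(seed = 4)
  u <- build_universe(sc$interactions, sc$annotations)
  targeted <- sort(unique(sc$interactions$entries$gene_id))
  expect_equal(u$gene_at, targeted)
  expect_equal(unname(u$index_of[targeted]), seq_along(targeted) - 1L)
})

test_that("per-miRNA bitsets have the miRNA's distinct target count", {
  sc <- small_scenario(seed = 2)
  u <- build_universe(sc$interactions, sc$annotations)
  map <- mirna_bitsets(sc$interactions, u)
  for (m in sample(map$mirna_ids, 10)) {
    expect_equal(bitset_cardinality(mirna_bitset(map, m)),
                 length(sc$truth$target_sets[[m]]))
    expect_setequal(bitset_genes(mirna_bitset(map, m), u),
                    sc$truth$target_sets[[m]])
  }
})

test_that("group union: identity, idempotence, fold-order invariance, oracle", {
  ints <- interactions_from_lines(c("miR-a,g1", "miR-a,g3", "miR-b,g2",
                                    "miR-b,g3", "miR-c,g4"))
  u <- build_universe(ints)
  map <- mirna_bitsets(ints, u)
  a <- mirna_bitset(map, "miR-a")
  zero <- target_bitset(integer(0), u)

  expect_identical(unclass(group_union(list(a, zero))), unclass(a))
  expect_identical(unclass(group_union(list(a, a))), unclass(a))
  expect_warning(z <- group_union(list(), width = u$size), "empty")
  expect_equal(bitset_cardinality(z), 0L)

  # {g1,g3} U {g2,g3} = {g1,g2,g3}
  ab <- group_union(list(a, mirna_bitset(map, "miR-b")))
  expect_equal(bitset_cardinality(ab), 3L)
  expect_equal(bitset_genes(ab, u), c("g1", "g2", "g3"))

  # any fold order gives the identical bit pattern
  members <- lapply(c("miR-a", "miR-b", "miR-c"), mirna_bitset, map = map)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_identical(unclass(group_union(members[perm])),
                     unclass(group_union(members)))
})

test_that("union cardinality is bounded by max member and sum of members", {
  sc <- small_scenario(seed = 6)
  u <- build_universe(sc$interactions, sc$annotations)
  map <- mirna_bitsets(sc$interactions, u)
  set.seed(30)
  for (i in 1:20) {
    ids <- sample(map$mirna_ids, 4)
    members <- lapply(ids, mirna_bitset, map = map)
    card <- bitset_cardinality(group_union(members))
    sizes <- vapply(members, bitset_cardinality, integer(1))
    expect_gte(card, max(sizes))
    expect_lte(card, sum(sizes))
    expect_equal(card, length(oracle_union(sc$truth$target_sets, ids)))
  }
})

test_that("probe_overlap matches the set oracle and respects its bounds", {
  ints <- interactions_from_lines(
    c("miR-a,g1", "miR-a,g3", "miR-a,g6", "miR-b,g8"))
  anns <- annotations_from_lines(
    c("g2,C1,c", "g3,C1,c", "g6,C1,c", "g8,C1,c", "g1,C2,d", "g3,C2,d"))
  u <- build_universe(ints, anns)
  cats <- build_category_index(anns, u)
  grp <- mirna_bitset(mirna_bitsets(ints, u), "miR-a") # {g1,g3,g6}

  # category C1 retains {g3,g6,g8}: overlap 2; C2 subset of group: overlap 2
  by_id <- setNames(cats, vapply(cats, `[[`, "", "category_id"))
  expect_equal(probe_overlap(grp, by_id$C1), 2L)
  expect_equal(probe_overlap(grp, by_id$C2), by_id$C2$size)

  # disjoint category
  disjoint <- list(category_id = "X", name = "X",
                   gene_bits = u$index_of[["g8"]], size = 1L)
  expect_equal(probe_overlap(grp, disjoint), 0L)
})

test_that("category index drops empty categories and keeps pre-filter sizes", {
  ints <- interactions_from_lines(c("miR-a,g1", "miR-b,g2"))
  anns <- annotations_from_lines(c("g1,C1,c1", "g9,C1,c1", "g9,C2,c2"))
  u <- build_universe(ints, anns)
  cats <- build_category_index(anns, u)
  expect_equal(length(cats), 1L)
  expect_equal(cats[[1]]$category_id, "C1")
  expect_equal(cats[[1]]$size, 1L)
  expect_equal(cats[[1]]$size_prefilter, 2L)
  expect_equal(attr(cats, "dropped"), "C2")
})

test_that("probe equals popcount(bitwise-and) on random instances", {
  sc <- small_scenario(seed = 8)
  u <- build_universe(sc$interactions, sc$annotations)
  map <- mirna_bitsets(sc$interactions, u)
  cats <- build_category_index(sc$annotations, u)
  set.seed(99)
  for (i in 1:50) {
    grp <- group_union(lapply(sample(map$mirna_ids, 3), mirna_bitset,
                              map = map))
    cat <- cats[[sample(length(cats), 1)]]
    cat_bs <- target_bitset(cat$gene_bits, u)
    probed <- probe_overlap(grp, cat)
    expect_identical(probed, popcount_overlap(grp, cat_bs))
    expect_lte(probed, min(bitset_cardinality(grp), cat$size))
  }
})

test_that("popcount_overlap rejects width mismatches", {
  ints <- interactions_from_lines(c("miR-a,g1", "miR-b,g2"))
  u <- build_universe(ints)
  a <- target_bitset(0L, u)
  b <- structure(integer(2), width = 64L, class = "target_bitset")
  expect_error(popcount_overlap(a, b), class = "mirset_logic_error")
})

test_that("operation counters tally union folds and probes", {
  sc <- small_scenario(seed = 10)
  u <- build_universe(sc$interactions, sc$annotations)
  map <- mirna_bitsets(sc$interactions, u)
  cats <- build_category_index(sc$annotations, u)
  counters <- mirset:::new_counters()
  group_union(lapply(map$mirna_ids[1:4], mirna_bitset, map = map),
              counters = counters)
  expect_equal(counters$unions, 4)
  grp <- group_union(lapply(map$mirna_ids[1:4], mirna_bitset, map = map))
  for (cat in cats[1:3]) probe_overlap(grp, cat, counters)
  expect_equal(counters$probes, sum(vapply(cats[1:3], `[[`, 0L, "size")))
})
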