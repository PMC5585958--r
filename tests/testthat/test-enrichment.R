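test_that("group sampling is seed-deterministic, size-checked and uniform", {
  mirnas <- sprintf("m%02d", 1:12)
  g1 <- sample_groups(mirnas, 4, 50, seed = 5)
  g2 <- sample_groups(mirnas, 4, 50, seed = 5)
  expect_identical(g1, g2)
  expect_true(all(vapply(g1, function(g) length(unique(g)) == 4L, logical(1))))
  expect_error(sample_groups(mirnas, 13, 5, seed = 1),
               class = "mirset_input_error")

  # size = all miRNAs: every group is the full set
  gall <- sample_groups(mirnas, 12, 5, seed = 2)
  for (g in gall) expect_setequal(g, mirnas)

  # size 1: each miRNA drawn with frequency ~ 1/M (99.9% binomial interval)
  n <- 6000
  draws <- unlist(sample_groups(mirnas, 1, n, seed = 7))
  counts <- table(factor(draws, levels = mirnas))
  lo <- qbinom(0.0005, n, 1 / 12)
  hi <- qbinom(0.9995, n, 1 / 12)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("pool union bitsets match the naive set oracle", {
  sc <- small_scenario(seed = 12)
  u <- build_universe(sc$interactions, sc$annotations)
  map <- mirna_bitsets(sc$interactions, u)
  groups <- sample_groups(map$mirna_ids, 5, 40, seed = 3)
  pool <- build_pool(groups, map)
  expect_equal(pool$n, 40L)
  for (i in seq_along(groups)) {
    bs <- structure(pool$words[, i], width = pool$width,
                    class = "target_bitset")
    expect_equal(bitset_cardinality(bs),
                 length(oracle_union(sc$truth$target_sets, groups[[i]])))
  }
  # identical groups produce identical bit patterns
  pool2 <- build_pool(list(groups[[1]], groups[[1]]), map)
  expect_identical(pool2$words[, 1], pool2$words[, 2])
  # a single group equal to the query reproduces the query union
  qbs <- group_union(lapply(groups[[1]], mirna_bitset, map = map))
  expect_identical(pool2$words[, 1], as.integer(unclass(qbs)))
  expect_error(build_pool(list(c("nope")), map), class = "mirset_logic_error")
})

test_that("empirical p-value boundary conventions", {
  ints <- interactions_from_lines(
    c("miR-a,g1", "miR-a,g2", "miR-b,g1", "miR-b,g2", "miR-c,g1", "miR-c,g2"))
  anns <- annotations_from_lines(c("g1,C1,c", "g2,C1,c"))
  u <- build_universe(ints, anns)
  map <- mirna_bitsets(ints, u)
  cat1 <- build_category_index(anns, u)[[1]]
  pool <- build_pool(sample_groups(map$mirna_ids, 2, 25, seed = 1), map)

  # query overlap at the category maximum: nothing can strictly exceed it
  strict <- empirical_pvalue(cat1$size, pool, cat1, run_config(seed = 1))
  expect_equal(strict$exceed_count, 0L)
  expect_equal(strict$p, 0)

  # all pool overlaps equal the query overlap: >= flips p from 0 to 1
  ge <- empirical_pvalue(cat1$size, pool, cat1,
                         run_config(seed = 1, strict_greater = FALSE))
  expect_equal(ge$p, 1)

  # plus-one correction keeps p strictly positive
  plus <- empirical_pvalue(cat1$size, pool, cat1,
                           run_config(seed = 1, plus_one_correction = TRUE))
  expect_equal(plus$p, 1 / 26)
})

test_that("p-values live on the 1/N grid and are monotone in query overlap", {
  sc <- small_scenario(seed = 14)
  u <- build_universe(sc$interactions, sc$annotations)
  map <- mirna_bitsets(sc$interactions, u)
  cats <- build_category_index(sc$annotations, u)
  pool <- build_pool(sample_groups(map$mirna_ids, 5, 200, seed = 21), map)
  cfg <- run_config(seed = 21)
  cat <- cats[[which.max(vapply(cats, `[[`, 0L, "size"))]]
  ps <- vapply(seq_len(cat$size), function(q)
    empirical_pvalue(q, pool, cat, cfg)$p, numeric(1))
  expect_identical(ps, round(ps * 200) / 200) # exact k/N grid values
  expect_true(all(diff(ps) <= 0))
})

test_that("full pipeline equals the naive set oracle on the same groups", {
  sc <- small_scenario(seed = 16)
  cfg <- run_config(iterations = 300, seed = 8)
  fit <- run_enrichment(sc$query, sc$interactions, sc$annotations, cfg)

  all_mirnas <- sort(unique(sc$interactions$entries$mirna_id),
                     method = "radix")
  groups <- sample_groups(all_mirnas, length(sc$query$mirna_ids), 300,
                          seed = 8)
  oracle <- oracle_enrichment(sc$truth$target_sets, sc$truth$categories,
                              sc$query$mirna_ids, groups)
  merged <- merge(fit$results, oracle, by = "category_id")
  expect_equal(nrow(merged), nrow(fit$results))
  expect_equal(merged$overlap_count, merged$overlap)
  expect_equal(merged$exceed_count, merged$exceed)
  expect_equal(merged$empirical_p_value, merged$p)
})

test_that("engines agree exactly and worker count does not change results", {
  sc <- small_scenario(seed = 18)
  cfg1 <- run_config(iterations = 400, seed = 31, workers = 1)
  cfg4 <- run_config(iterations = 400, seed = 31, workers = 4)
  bit1 <- run_enrichment(sc$query, sc$interactions, sc$annotations, cfg1)
  bit4 <- run_enrichment(sc$query, sc$interactions, sc$annotations, cfg4)
  naive <- run_enrichment(sc$query, sc$interactions, sc$annotations, cfg1,
                          engine = "naive")
  expect_identical(bit1$results, bit4$results)
  expect_identical(bit1$results, naive$results)
  expect_equal(bit1$report$union_ops, naive$report$union_ops)
  expect_equal(bit1$report$probe_ops, naive$report$probe_ops)
})

test_that("operation counters follow the N x group-size contract", {
  sc <- small_scenario(seed = 20, query_size = 6)
  n <- 250
  cfg <- run_config(iterations = n, seed = 2)
  fit <- run_enrichment(sc$query, sc$interactions, sc$annotations, cfg)
  size <- fit$report$group_size
  expect_equal(fit$report$union_ops_pool, n * size)
  expect_equal(fit$report$union_ops_query, size)
  expect_equal(fit$report$union_ops, n * size + size)

  # probes: every category once for the query, tested categories N times
  u <- build_universe(sc$interactions, sc$annotations)
  cats <- build_category_index(sc$annotations, u)
  sizes <- vapply(cats, `[[`, 0L, "size")
  ids <- vapply(cats, `[[`, "", "category_id")
  tested <- fit$results$category_id[!is.na(fit$results$empirical_p_value)]
  expect_equal(fit$report$probe_ops,
               sum(sizes) + n * sum(sizes[ids %in% tested]))
})

test_that("zero-overlap categories are excluded and degenerate queries handled", {
  # query targets only g9; category C1 never overlaps it
  ints <- interactions_from_lines(
    c("miR-q,g9", "miR-a,g1", "miR-b,g2", "miR-c,g3"))
  anns <- annotations_from_lines(c("g1,C1,c", "g2,C1,c"))
  q <- query_group("miR-q")
  expect_warning(
    fit <- run_enrichment(q, ints, anns, run_config(iterations = 50, seed = 1)),
    "no category tested")
  expect_true(all(is.na(fit$results$empirical_p_value)))
  expect_true(all(is.na(fit$results$significance)))
  expect_equal(fit$results$overlap_count, 0L)
  expect_equal(fit$report$m_tested, 0L)

  # absent query members dropped with warning; none left is fatal
  expect_warning(
    run_enrichment(query_group(c("miR-a", "ghost")), ints, anns,
                   run_config(iterations = 20, seed = 1)),
    "absent")
  expect_error(
    suppressWarnings(run_enrichment(query_group("ghost"), ints, anns,
                                    run_config(iterations = 20, seed = 1))),
    class = "mirset_input_error")

  # query = full miRNA set: every random group equals it, so strict p = 0
  qall <- query_group(c("miR-q", "miR-a", "miR-b", "miR-c"))
  fit2 <- run_enrichment(qall, ints, anns, run_config(iterations = 30, seed = 1))
  tested <- !is.na(fit2$results$empirical_p_value)
  expect_true(any(tested))
  expect_true(all(fit2$results$empirical_p_value[tested] == 0))
})

test_that("a planted enriched category attains the smallest empirical p", {
  sc <- generate_scenario(scenario_config(
    n_mirnas = 80, n_genes = 800, target_count_law = c(log(20), 0.7),
    min_targets = 5, max_targets = 80, shared_pool_fraction = 0.2,
    n_categories = 20, category_size_range = c(10, 25),
    planted = list(category_id = "C005", query_size = 6,
                   coverage_fraction = 0.9),
    seed = 42))
  fit <- run_enrichment(sc$query, sc$interactions, sc$annotations,
                        run_config(iterations = 1000, seed = 17))
  best <- min(fit$results$empirical_p_value, na.rm = TRUE)
  expect_equal(
    fit$results$empirical_p_value[fit$results$category_id == "C005"], best)
})
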