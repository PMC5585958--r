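#' Monte Carlo run configuration
#'
#' @param iterations Number of random miRNA groups `N`. Common presets are
#'   10000 (fast, low accuracy), 100000 and 1000000 (accuracy-grade); the
#'   p-value granularity is `1/N`.
#' @param seed Integer seed; a single pseudo-random stream seeded from it
#'   drives all sampling, which happens before any parallel section, so
#'   results are invariant to the worker count.
#' @param workers Number of parallel workers for the per-category p-value
#'   pass (forked via the parallel package; categories are partitioned into
#'   contiguous chunks).
#' @param alpha_levels FDR levels `(alpha1, alpha2)` for the `"*"` and `"**"`
#'   marks; must satisfy `0 < alpha2 < alpha1 < 1`.
#' @param strict_greater If `TRUE` (default) a random group counts toward the
#'   p-value only when its overlap strictly exceeds the query's; `FALSE`
#'   uses greater-or-equal.
#' @param plus_one_correction If `TRUE`, report `(k + 1) / (N + 1)` instead of
#'   `k / N`, which avoids exact zeros.
#' @param exclude_query_from_sampling If `TRUE`, random groups are drawn from
#'   the non-query miRNAs only. Default `FALSE`: random groups are assembled
#'   from all miRNAs in the interaction table.
#' @param include_annotation_only_genes Passed to [build_universe()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(iterations = 10000L, seed = 42L, workers = 1L,
                       alpha_levels = c(0.05, 0.01), strict_greater = TRUE,
                       plus_one_correction = FALSE,
                       exclude_query_from_sampling = FALSE,
                       include_annotation_only_genes = FALSE) {
  iterations <- as.integer(iterations)
  workers <- as.integer(workers)
  if (is.na(iterations) || iterations < 1L)
    ms_input_error("iterations must be >= 1")
  if (is.na(workers) || workers < 1L)
    ms_input_error("workers must be >= 1")
  if (length(alpha_levels) != 2L || !(alpha_levels[2L] < alpha_levels[1L]) ||
      alpha_levels[2L] <= 0 || alpha_levels[1L] >= 1)
    ms_input_error("alpha_levels must satisfy 0 < alpha2 < alpha1 < 1")
  structure(list(iterations = iterations, seed = as.integer(seed),
                 workers = workers, alpha_levels = as.numeric(alpha_levels),
                 strict_greater = isTRUE(strict_greater),
                 plus_one_correction = isTRUE(plus_one_correction),
                 exclude_query_from_sampling = isTRUE(exclude_query_from_sampling),
                 include_annotation_only_genes = isTRUE(include_annotation_only_genes)),
            class = "run_config")
}

#' Sample random miRNA groups
#'
#' Each group is a uniform without-replacement sample of `size` distinct
#' miRNAs; groups may repeat across draws. Fully determined by `seed`
#' (the caller's RNG state is preserved).
#'
#' @param all_mirnas Character vector of candidate miRNA identifiers.
#' @param size Group size (the query group's size).
#' @param n Number of groups to draw.
#' @param seed Integer seed.
#' @return List of `n` character vectors of length `size`.
#' @export
sample_groups <- function(all_mirnas, size, n, seed) {
  if (size > length(all_mirnas))
    ms_input_error(sprintf(
      "group size %d exceeds the %d available miRNAs", size, length(all_mirnas)))
  with_seed(seed, lapply(seq_len(n), function(i) sample(all_mirnas, size)))
}

#' Enumerate all possible miRNA groups of a given size
#'
#' Replaces Monte Carlo sampling with exhaustive enumeration, for exact
#' p-values on tiny instances (pass the result as the `groups` argument of
#' [run_enrichment()]).
#'
#' @inheritParams sample_groups
#' @return List of all `choose(length(all_mirnas), size)` groups.
#' @export
enumerate_groups <- function(all_mirnas, size) {
  if (size > length(all_mirnas))
    ms_input_error("group size exceeds the available miRNAs")
  combs <- utils::combn(all_mirnas, size, simplify = FALSE)
  combs
}

#' Materialize the random-group union bitsets
#'
#' Folds every group's member bitsets into one union bitset per group
#' (bitwise-or), stored column-wise in a single integer matrix that all
#' workers read. The union counter is incremented by one fold step per
#' member.
#'
#' @param groups List of character vectors (miRNA ids).
#' @param bitset_map A `mirna_bitset_map` covering every member.
#' @param counters Optional counter environment.
#' @return An object of class `random_group_pool` with fields `words`
#'   (`n_words` x `n` integer matrix), `groups`, `n` and `width`.
#' @export
build_pool <- function(groups, bitset_map, counters = NULL) {
  idx <- lapply(groups, function(g) {
    j <- match(g, bitset_map$mirna_ids)
    if (anyNA(j))
      ms_logic_error(paste0("no bitset for miRNA ",
                            paste(g[is.na(j)], collapse = ", ")))
    j
  })
  words <- bs_pool_build(bitset_map$words, idx)
  if (!is.null(counters))
    counters$unions <- counters$unions + sum(lengths(groups))
  structure(list(words = words, groups = groups, n = length(groups),
                 width = bitset_map$width),
            class = "random_group_pool")
}

# Bit-probe one category against the whole pool; returns integer overlaps.
pool_overlaps <- function(pool, category, counters = NULL) {
  if (!is.null(counters))
    counters$probes <- counters$probes + pool$n * category$size
  bs_pool_probe(pool$words, category$gene_bits)
}

#' Empirical p-value for one category
#'
#' The p-value is the fraction of random groups whose overlap with the
#' category exceeds the query group's overlap (strictly, by default).
#' Comparing counts is equivalent to comparing overlap proportions because
#' the category size is constant within a category.
#'
#' @param query_overlap Integer query overlap (must be >= 1; zero-overlap
#'   categories are excluded upstream).
#' @param pool A `random_group_pool`.
#' @param category A category index element.
#' @param config A `run_config`.
#' @param counters Optional counter environment.
#' @return List with `exceed_count` and `p`.
#' @export
empirical_pvalue <- function(query_overlap, pool, category, config = run_config(),
                             counters = NULL) {
  ov <- pool_overlaps(pool, category, counters)
  exceed <- if (config$strict_greater) sum(ov > query_overlap)
            else sum(ov >= query_overlap)
  p <- if (config$plus_one_correction) (exceed + 1) / (pool$n + 1)
       else exceed / pool$n
  list(exceed_count = as.integer(exceed), p = p)
}

# Contiguous partition of indices into at most `workers` chunks.
chunk_indices <- function(idx, workers) {
  if (length(idx) == 0L) return(list())
  k <- min(workers, length(idx))
  split(idx, ceiling(seq_along(idx) / (length(idx) / k)))
}

#' Run the unbiased miRNA functional enrichment analysis
#'
#' The full pipeline: build the gene universe and per-miRNA target bitsets,
#' form the query group's union bitset, compute its overlap with every
#' annotation category, exclude categories sharing no gene with the query
#' targets, sample one pool of `N` random same-size miRNA groups (reused for
#' every category), compute per-category empirical p-values, and mark
#' Benjamini-Hochberg significance at the configured FDR levels.
#'
#' Two engines implement the identical contract: `"bitset"` (bitwise-or
#' unions, bit-probing intersections) and `"naive"` (hash-set unions, size-
#' only hash-join intersections). For a given seed they produce identical
#' results; the naive engine exists as a user-runnable oracle.
#'
#' @param query A `query_group`. Members absent from the interaction table
#'   are dropped with a warning; if none remain the run aborts.
#' @param interactions An `interaction_table`.
#' @param annotations An `annotation_table`.
#' @param config A [run_config()].
#' @param engine `"bitset"` or `"naive"`.
#' @param groups Optional explicit list of groups (e.g. from
#'   [enumerate_groups()]) overriding Monte Carlo sampling.
#' @return List with `results` (data frame: `category_id`, `category_name`,
#'   `category_size`, `overlap_count`, `overlap_proportion`,
#'   `empirical_p_value`, `exceed_count`, `significance`) sorted by ascending
#'   p-value, and `report` (engine, seed, N, group size, operation counters,
#'   dropped identifiers, number of tested categories `m`, timing).
#' @export
run_enrichment <- function(query, interactions, annotations,
                           config = run_config(),
                           engine = c("bitset", "naive"), groups = NULL) {
  engine <- match.arg(engine)
  t0 <- proc.time()[["elapsed"]]

  all_mirnas <- radix_sort(unique(interactions$entries$mirna_id))
  present <- query$mirna_ids %in% all_mirnas
  dropped_query <- query$mirna_ids[!present]
  if (length(dropped_query) > 0L)
    warning(sprintf("%d query miRNA(s) absent from the interaction table dropped: %s",
                    length(dropped_query),
                    paste(head(dropped_query, 5L), collapse = ", ")),
            call. = FALSE)
  query_ids <- query$mirna_ids[present]
  if (length(query_ids) == 0L)
    ms_input_error("no query miRNA is present in the interaction table")

  universe <- build_universe(interactions, annotations,
                             config$include_annotation_only_genes)
  categories <- build_category_index(annotations, universe)
  counters <- new_counters()

  # One pool per run, sampled before any parallel work.
  if (is.null(groups)) {
    pool_candidates <- if (config$exclude_query_from_sampling)
      setdiff(all_mirnas, query_ids) else all_mirnas
    groups <- sample_groups(pool_candidates, length(query_ids),
                            config$iterations, config$seed)
  }
  n_iter <- length(groups)

  eng <- if (engine == "bitset") engine_bitset else engine_naive
  out <- eng(query_ids, interactions, universe, categories, groups,
             config, counters)

  cat_size <- vapply(categories, function(x) x$size, integer(1))
  results <- data.frame(
    category_id = vapply(categories, function(x) x$category_id, character(1)),
    category_name = vapply(categories, function(x) x$name, character(1)),
    category_size = cat_size,
    overlap_count = out$query_overlaps,
    overlap_proportion = out$query_overlaps / cat_size,
    empirical_p_value = out$p,
    exceed_count = out$exceed,
    stringsAsFactors = FALSE)
  results <- bh_mark(results, config$alpha_levels)$results
  results <- sort_results(results)

  if (sum(out$query_overlaps > 0L) == 0L)
    warning("query targets share no gene with any annotation category; no category tested",
            call. = FALSE)

  report <- list(engine = engine, seed = config$seed, iterations = n_iter,
                 group_size = length(query_ids), workers = config$workers,
                 union_ops = counters$unions, probe_ops = counters$probes,
                 union_ops_query = out$union_ops_query,
                 union_ops_pool = out$union_ops_pool,
                 m_tested = sum(!is.na(results$empirical_p_value)),
                 n_categories = length(categories),
                 dropped_query_ids = dropped_query,
                 dropped_categories = attr(categories, "dropped"),
                 universe_size = universe$size,
                 n_mirnas = length(all_mirnas),
                 elapsed_seconds = proc.time()[["elapsed"]] - t0)
  list(results = results, report = report)
}

# Bitset engine: bitwise-or unions, bit-probing intersections.
engine_bitset <- function(query_ids, interactions, universe, categories,
                          groups, config, counters) {
  map <- mirna_bitsets(interactions, universe)

  u0 <- counters$unions
  query_union <- group_union(lapply(query_ids, mirna_bitset, map = map),
                             width = universe$size, counters = counters)
  union_ops_query <- counters$unions - u0

  query_overlaps <- vapply(categories, function(cat)
    probe_overlap(query_union, cat, counters), integer(1))

  u1 <- counters$unions
  pool <- build_pool(groups, map, counters)
  union_ops_pool <- counters$unions - u1

  tested <- which(query_overlaps > 0L)
  n <- pool$n
  p <- rep(NA_real_, length(categories))
  exceed <- rep(NA_integer_, length(categories))

  chunks <- chunk_indices(tested, config$workers)
  run_chunk <- function(idx) {
    local_counters <- new_counters()
    res <- lapply(idx, function(i)
      empirical_pvalue(query_overlaps[i], pool, categories[[i]], config,
                       local_counters))
    list(idx = idx, res = res, probes = local_counters$probes)
  }
  chunk_out <- if (config$workers > 1L && length(chunks) > 1L)
    parallel::mclapply(chunks, run_chunk, mc.cores = config$workers)
  else lapply(chunks, run_chunk)

  for (co in chunk_out) {
    counters$probes <- counters$probes + co$probes
    for (k in seq_along(co$idx)) {
      i <- co$idx[k]
      exceed[i] <- co$res[[k]]$exceed_count
      p[i] <- co$res[[k]]$p
    }
  }
  list(query_overlaps = query_overlaps, p = p, exceed = exceed,
       union_ops_query = union_ops_query, union_ops_pool = union_ops_pool)
}
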