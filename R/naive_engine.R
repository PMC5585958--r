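# Naive reference engine: plain hash-set algebra. Unions are hash-based
# (`unique` on concatenated id vectors); intersection sizes use a single
# hash-join probe pass per group over the concatenated category genes,
# producing only the size, never the intersection set. This engine is the
# user-runnable oracle for the bitset engine: same sampled groups, same
# counters, identical results.
engine_naive <- function(query_ids, interactions, universe, categories,
                         groups, config, counters) {
  # per-miRNA target sets restricted to the universe (identical retained
  # gene set as the bitset engine)
  ent <- interactions$entries
  keep <- ent$gene_id %in% universe$gene_at
  target_sets <- split(ent$gene_id[keep], ent$mirna_id[keep])

  hash_union <- function(ids) {
    acc <- character(0)
    for (m in ids) acc <- unique(c(acc, target_sets[[m]]))
    counters$unions <- counters$unions + length(ids)
    acc
  }

  u0 <- counters$unions
  query_set <- hash_union(query_ids)
  union_ops_query <- counters$unions - u0

  cat_genes <- lapply(categories, function(cat)
    universe$gene_at[cat$gene_bits + 1L])
  cat_size <- vapply(categories, function(x) x$size, integer(1))

  # query pass probes every category
  query_overlaps <- vapply(cat_genes, function(g) sum(g %in% query_set),
                           integer(1))
  counters$probes <- counters$probes + sum(cat_size)

  u1 <- counters$unions
  pool_sets <- lapply(groups, hash_union)
  union_ops_pool <- counters$unions - u1

  tested <- which(query_overlaps > 0L)
  n <- length(groups)
  p <- rep(NA_real_, length(categories))
  exceed <- rep(NA_integer_, length(categories))

  if (length(tested) > 0L) {
    probe_genes <- unlist(cat_genes[tested], use.names = FALSE)
    probe_cat <- rep(seq_along(tested), cat_size[tested])
    exceed_tested <- integer(length(tested))
    for (gs in pool_sets) {
      hits <- probe_genes %in% gs             # hash-join, size only
      ov <- tabulate(probe_cat[hits], nbins = length(tested))
      exceed_tested <- exceed_tested +
        if (config$strict_greater) (ov > query_overlaps[tested])
        else (ov >= query_overlaps[tested])
    }
    counters$probes <- counters$probes + n * sum(cat_size[tested])
    exceed[tested] <- exceed_tested
    p[tested] <- if (config$plus_one_correction) (exceed_tested + 1) / (n + 1)
                 else exceed_tested / n
  }
  list(query_overlaps = query_overlaps, p = p, exceed = exceed,
       union_ops_query = union_ops_query, union_ops_pool = union_ops_pool)
}
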