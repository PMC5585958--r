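# Fixture builders shared across test files. All fixtures are generated in
# code; file-based ones go through temporary files.

write_tmp_lines <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Interaction/annotation tables from literal pair/triple text, via the I/O
# layer itself.
interactions_from_lines <- function(lines, config = io_config()) {
  read_interactions(write_tmp_lines(lines), config)
}
annotations_from_lines <- function(lines, config = io_config()) {
  read_annotations(write_tmp_lines(lines), config)
}

# A small synthetic scenario sized for fast tests.
small_scenario <- function(seed = 1, n_mirnas = 60, n_genes = 500,
                           n_categories = 15, query_size = 5, ...) {
  generate_scenario(scenario_config(
    n_mirnas = n_mirnas, n_genes = n_genes,
    target_count_law = c(log(25), 0.8), min_targets = 5, max_targets = 120,
    shared_pool_fraction = 0.3, n_categories = n_categories,
    category_size_range = c(8, 25), query_size = query_size, seed = seed, ...))
}

# Independent set-algebra oracle: plain sorted character sets.
oracle_union <- function(target_sets, members) {
  sort(unique(unlist(target_sets[members], use.names = FALSE)))
}
oracle_overlap <- function(set_a, set_b) length(intersect(set_a, set_b))

# Independent full-pipeline oracle: given explicit groups, compute per
# category (overlap, exceed count, p) with plain sets.
oracle_enrichment <- function(target_sets, categories, query_ids, groups,
                              strict = TRUE, plus_one = FALSE) {
  universe_genes <- sort(unique(unlist(target_sets, use.names = FALSE)))
  cats <- lapply(categories, function(g) intersect(g, universe_genes))
  cats <- cats[lengths(cats) > 0]
  qset <- oracle_union(target_sets, query_ids)
  gsets <- lapply(groups, function(g) oracle_union(target_sets, g))
  n <- length(groups)
  res <- lapply(names(cats), function(cid) {
    cg <- cats[[cid]]
    qov <- oracle_overlap(qset, cg)
    if (qov == 0) {
      return(data.frame(category_id = cid, overlap = 0L,
                        exceed = NA_integer_, p = NA_real_))
    }
    ov <- vapply(gsets, oracle_overlap, integer(1), set_b = cg)
    exceed <- if (strict) sum(ov > qov) else sum(ov >= qov)
    p <- if (plus_one) (exceed + 1) / (n + 1) else exceed / n
    data.frame(category_id = cid, overlap = qov,
               exceed = as.integer(exceed), p = p)
  })
  do.call(rbind, res)
}

# Independent Benjamini-Hochberg step-up oracle.
oracle_bh_significant <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * alpha / m)
  sig <- rep(FALSE, m)
  if (length(k) > 0) sig[ord[seq_len(max(k))]] <- TRUE
  sig
}

file_bytes <- function(path) readBin(path, "raw", file.size(path))
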