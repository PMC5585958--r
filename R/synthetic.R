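#' Synthetic scenario configuration
#'
#' Describes a synthetic miRNA-target / annotation dataset. Per-miRNA target
#' counts follow a log-normal law truncated to `[min_targets, max_targets]`
#' — predicted-target catalogues are strongly right-skewed, with single
#' miRNAs targeting from tens to thousands of genes. Target correlation
#' between miRNAs is induced by a shared "hub" gene pool: each miRNA draws a
#' fraction `shared_pool_fraction` of its targets from the hub pool (a fixed
#' random subset of `hub_fraction` of all genes) and the rest uniformly from
#' the remaining genes. At `shared_pool_fraction = 0` target sets are
#' independent uniform draws; as it approaches 1 all miRNAs concentrate on
#' the hub and pairwise target overlap grows.
#'
#' @param n_mirnas Number of miRNAs.
#' @param n_genes Number of genes.
#' @param target_count_law `c(meanlog, sdlog)` of the log-normal target-count
#'   law (before truncation and rounding).
#' @param min_targets,max_targets Truncation bounds (inclusive) for the
#'   per-miRNA target count; `max_targets <= n_genes`.
#' @param shared_pool_fraction Fraction of each miRNA's targets drawn from
#'   the hub pool, in `[0, 1)`.
#' @param hub_fraction Hub pool size as a fraction of `n_genes`.
#' @param n_categories Number of annotation categories.
#' @param category_size_range `c(min, max)`; sizes drawn uniformly.
#' @param category_hub_bias Fraction of each category's genes drawn from the
#'   hub pool, in `[0, 1)`. At 0 (default) category members are uniform over
#'   all genes. Positive values encode an annotation structure correlated
#'   with targeting propensity — well-annotated genes tend to be the
#'   frequently predicted targets — which is the regime where the gene-level
#'   Fisher test becomes anti-conservative for miRNA-group queries.
#' @param query_size Query group size when nothing is planted.
#' @param planted Optional `list(category_id =, query_size =,
#'   coverage_fraction =)`: the query group is constructed so that its union
#'   covers at least `coverage_fraction` of the planted category.
#' @param seed Integer seed; a fixed seed yields byte-identical files from
#'   [write_scenario()].
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_mirnas = 500L, n_genes = 5000L,
                            target_count_law = c(meanlog = log(300), sdlog = 1),
                            min_targets = 10L, max_targets = 4000L,
                            shared_pool_fraction = 0.3, hub_fraction = 0.1,
                            n_categories = 50L,
                            category_size_range = c(10L, 50L),
                            category_hub_bias = 0,
                            query_size = 10L, planted = NULL, seed = 1L) {
  if (min_targets < 1L) ms_input_error("min_targets must be >= 1")
  if (max_targets > n_genes) ms_input_error("max_targets must be <= n_genes")
  if (min_targets > max_targets) ms_input_error("min_targets > max_targets")
  if (shared_pool_fraction < 0 || shared_pool_fraction >= 1)
    ms_input_error("shared_pool_fraction must lie in [0, 1)")
  if (category_size_range[2L] > n_genes)
    ms_input_error("category sizes must be <= n_genes")
  if (category_hub_bias < 0 || category_hub_bias >= 1)
    ms_input_error("category_hub_bias must lie in [0, 1)")
  if (!is.null(planted)) {
    need <- c("category_id", "query_size", "coverage_fraction")
    if (!all(need %in% names(planted)))
      ms_input_error("planted needs category_id, query_size, coverage_fraction")
    if (planted$coverage_fraction < 0 || planted$coverage_fraction > 1)
      ms_input_error("coverage_fraction must lie in [0, 1]")
    if (planted$query_size > n_mirnas)
      ms_input_error("planted query_size exceeds n_mirnas: planting infeasible")
    if (planted$query_size < 1L)
      ms_input_error("planted query_size must be >= 1: planting infeasible")
  } else if (query_size > n_mirnas) {
    ms_input_error("query_size exceeds n_mirnas")
  }
  structure(list(n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
                 target_count_law = target_count_law,
                 min_targets = as.integer(min_targets),
                 max_targets = as.integer(max_targets),
                 shared_pool_fraction = shared_pool_fraction,
                 hub_fraction = hub_fraction,
                 n_categories = as.integer(n_categories),
                 category_size_range = as.integer(category_size_range),
                 category_hub_bias = category_hub_bias,
                 query_size = as.integer(query_size), planted = planted,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Truncated log-normal draws by rejection, rounded to integers. Truncation
# happens on the continuous scale so rounding stays inside the bounds.
rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x >= lower & x <= upper])
  }
  as.integer(round(out[seq_len(n)]))
}

#' Generate a synthetic interaction/annotation/query scenario
#'
#' Returns in-memory tables of exactly the classes the I/O layer produces,
#' plus a `truth` record of every draw for bookkeeping assertions. When a
#' category is planted, the query miRNAs are first sampled and then given
#' the required category genes (round-robin extra interaction pairs) so the
#' query union covers at least `coverage_fraction` of the category.
#'
#' @param config A [scenario_config()].
#' @return List with `interactions` (`interaction_table`), `annotations`
#'   (`annotation_table`), `query` (`query_group`) and `truth` (list:
#'   `genes`, `mirnas`, `hub`, `target_sets`, `target_counts`, `categories`,
#'   `query`, `planted`).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed(config$seed, {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    mirnas <- sprintf("mir-%04d", seq_len(config$n_mirnas))
    hub_size <- max(1L, as.integer(round(config$hub_fraction * config$n_genes)))
    hub <- sample(genes, hub_size)

    law <- config$target_count_law
    t_counts <- rtrunc_lnorm(config$n_mirnas, law[[1L]], law[[2L]],
                             config$min_targets, config$max_targets)

    target_sets <- lapply(seq_len(config$n_mirnas), function(i) {
      t <- t_counts[i]
      n_hub <- min(as.integer(round(config$shared_pool_fraction * t)), hub_size)
      hub_sel <- if (n_hub > 0L) sample(hub, n_hub) else character(0)
      free <- sample(setdiff(genes, hub_sel), t - n_hub)
      c(hub_sel, free)
    })
    names(target_sets) <- mirnas

    size_lo <- config$category_size_range[1L]
    size_hi <- config$category_size_range[2L]
    sizes <- size_lo +
      sample.int(size_hi - size_lo + 1L, config$n_categories,
                 replace = TRUE) - 1L
    cat_ids <- sprintf("C%03d", seq_len(config$n_categories))
    categories <- lapply(sizes, function(s) {
      n_hub <- min(as.integer(round(config$category_hub_bias * s)), hub_size)
      hub_sel <- if (n_hub > 0L) sample(hub, n_hub) else character(0)
      c(hub_sel, sample(setdiff(genes, hub_sel), s - n_hub))
    })
    names(categories) <- cat_ids

    planted <- config$planted
    if (is.null(planted)) {
      query_ids <- sample(mirnas, config$query_size)
      planted_rec <- NULL
    } else {
      if (!planted$category_id %in% cat_ids)
        ms_input_error(paste0("planted category not generated: ",
                              planted$category_id,
                              " (planting infeasible)"))
      query_ids <- sample(mirnas, planted$query_size)
      members <- categories[[planted$category_id]]
      required <- ceiling(planted$coverage_fraction * length(members))
      assigned <- if (required > 0L) sample(members, required) else character(0)
      # round-robin the required genes into the query miRNAs' target sets
      slot <- rep_len(query_ids, length(assigned))
      for (k in seq_along(assigned)) {
        m <- slot[k]
        target_sets[[m]] <- unique(c(target_sets[[m]], assigned[k]))
      }
      planted_rec <- list(category_id = planted$category_id,
                          coverage_fraction = planted$coverage_fraction,
                          required = required, assigned = assigned)
    }

    interactions <- new_interaction_table(
      data.frame(mirna_id = rep(mirnas, lengths(target_sets)),
                 gene_id = unlist(target_sets, use.names = FALSE),
                 stringsAsFactors = FALSE),
      report = list(synthetic = TRUE))
    annotations <- new_annotation_table(
      data.frame(gene_id = unlist(categories, use.names = FALSE),
                 category_id = rep(cat_ids, lengths(categories)),
                 category_name = rep(paste0("process_", cat_ids),
                                     lengths(categories)),
                 stringsAsFactors = FALSE),
      report = list(synthetic = TRUE))

    list(interactions = interactions, annotations = annotations,
         query = query_group(query_ids),
         truth = list(genes = genes, mirnas = mirnas, hub = hub,
                      target_sets = target_sets,
                      target_counts = lengths(target_sets),
                      categories = categories, query = query_ids,
                      planted = planted_rec))
  })
}

#' Write a scenario to input files
#'
#' Emits `interactions.csv`, `annotations.csv` and `query.txt` in the
#' formats [read_interactions()], [read_annotations()] and [read_query()]
#' parse, so a round trip reproduces the in-memory tables.
#'
#' @param scenario Output of [generate_scenario()].
#' @param dir Output directory (created if missing).
#' @param delimiter Field separator.
#' @return Named character vector of the three file paths.
#' @export
write_scenario <- function(scenario, dir, delimiter = ",") {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    ms_io_error(paste0("cannot create directory ", dir))
  paths <- c(interactions = file.path(dir, "interactions.csv"),
             annotations = file.path(dir, "annotations.csv"),
             query = file.path(dir, "query.txt"))
  ie <- scenario$interactions$entries
  writeLines(paste(ie$mirna_id, ie$gene_id, sep = delimiter),
             paths[["interactions"]])
  ae <- scenario$annotations$entries
  writeLines(paste(ae$gene_id, ae$category_id, ae$category_name,
                   sep = delimiter), paths[["annotations"]])
  writeLines(scenario$query$mirna_ids, paths[["query"]])
  paths
}
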