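#' I/O configuration
#'
#' Controls how delimited input files are parsed. miRNA nomenclature is
#' case-significant (`miR` vs `mir`), so identifiers are compared
#' case-sensitively unless `case_fold = TRUE`.
#'
#' @param delimiter Single field-separator character (default comma; tab and
#'   pipe are common alternatives in prediction exports).
#' @param header If `TRUE` the first non-comment line of each file is skipped.
#'   There is no auto-detection.
#' @param case_fold If `TRUE`, identifiers are lower-cased after trimming.
#' @param on_malformed `"warn"` skips malformed lines with a warning;
#'   `"fatal"` aborts on the first one.
#' @param comment_char Lines starting with this character are ignored.
#' @return A list of class `io_config`.
#' @export
io_config <- function(delimiter = ",", header = FALSE, case_fold = FALSE,
                      on_malformed = c("warn", "fatal"), comment_char = "#") {
  if (!is.character(delimiter) || nchar(delimiter) != 1L)
    ms_input_error("delimiter must be a single character")
  structure(list(delimiter = delimiter, header = isTRUE(header),
                 case_fold = isTRUE(case_fold),
                 on_malformed = match.arg(on_malformed),
                 comment_char = comment_char),
            class = "io_config")
}

#' Normalize an identifier
#'
#' Trims surrounding whitespace and optionally case-folds. Idempotent:
#' `normalize_id(normalize_id(x)) == normalize_id(x)`.
#'
#' @param x Character vector of identifiers.
#' @param case_fold Lower-case after trimming?
#' @return Character vector.
#' @export
normalize_id <- function(x, case_fold = FALSE) {
  y <- trimws(x)
  if (case_fold) y <- tolower(y)
  y
}

# Shared line reader: drops empty and comment lines, optionally the header,
# and splits fields. Returns list(fields = list of char vectors, raw_lines).
read_fields <- function(path, config) {
  if (!file.exists(path)) ms_io_error(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  raw_lines <- length(lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), config$comment_char)
  lines <- lines[keep]
  if (config$header && length(lines) >= 1L) lines <- lines[-1L]
  list(fields = strsplit(lines, config$delimiter, fixed = TRUE),
       raw_lines = raw_lines)
}

handle_malformed <- function(n_bad, what, config) {
  if (n_bad == 0L) return(invisible())
  msg <- sprintf("%d malformed line(s) skipped while reading %s", n_bad, what)
  if (config$on_malformed == "fatal") ms_format_error(msg)
  warning(msg, call. = FALSE)
}

#' Read a miRNA-to-gene interaction table
#'
#' Parses a delimited text file with the miRNA identifier in column 1 and the
#' gene identifier in column 2 (extra columns ignored). Duplicate
#' (miRNA, gene) pairs are collapsed. The returned object carries a load
#' report (raw line count, collapsed pair count, skipped malformed lines).
#'
#' @param path Path to the interaction file.
#' @param config An [io_config()].
#' @return An object of class `interaction_table` with elements `entries`
#'   (data frame with columns `mirna_id`, `gene_id`) and `report`.
#' @export
read_interactions <- function(path, config = io_config()) {
  parsed <- read_fields(path, config)
  fields <- parsed$fields
  ok <- vapply(fields, function(f) length(f) >= 2L &&
                 nzchar(trimws(f[1L])) && nzchar(trimws(f[2L])), logical(1))
  handle_malformed(sum(!ok), path, config)
  fields <- fields[ok]
  if (length(fields) == 0L)
    ms_format_error(paste0("no valid interaction records in ", path))
  mirna <- normalize_id(vapply(fields, `[`, character(1), 1L), config$case_fold)
  gene  <- normalize_id(vapply(fields, `[`, character(1), 2L), config$case_fold)
  dup <- duplicated(paste0(mirna, "\r", gene))
  entries <- data.frame(mirna_id = mirna[!dup], gene_id = gene[!dup],
                        stringsAsFactors = FALSE)
  new_interaction_table(entries,
                        report = list(raw_lines = parsed$raw_lines,
                                      collapsed_pairs = nrow(entries),
                                      skipped = sum(!ok)))
}

new_interaction_table <- function(entries, report = list()) {
  structure(list(entries = entries, report = report),
            class = "interaction_table")
}

#' Read a gene-to-annotation-category table
#'
#' Parses a delimited file with gene identifier in column 1, category
#' identifier in column 2 and (optionally) the category name in column 3;
#' a missing name defaults to the category identifier. Duplicate
#' (gene, category) pairs are collapsed; if a category appears with
#' conflicting names the first name wins and a warning is logged. Genes never
#' seen in an interaction table are retained here — whether they enter the
#' gene universe is decided by [build_universe()].
#'
#' @inheritParams read_interactions
#' @return An object of class `annotation_table` with elements `entries`
#'   (data frame with columns `gene_id`, `category_id`, `category_name`) and
#'   `report`.
#' @export
read_annotations <- function(path, config = io_config()) {
  parsed <- read_fields(path, config)
  fields <- parsed$fields
  ok <- vapply(fields, function(f) length(f) >= 2L &&
                 nzchar(trimws(f[1L])) && nzchar(trimws(f[2L])), logical(1))
  handle_malformed(sum(!ok), path, config)
  fields <- fields[ok]
  if (length(fields) == 0L)
    ms_format_error(paste0("no valid annotation records in ", path))
  gene <- normalize_id(vapply(fields, `[`, character(1), 1L), config$case_fold)
  cat_id <- normalize_id(vapply(fields, `[`, character(1), 2L), config$case_fold)
  cat_name <- vapply(fields, function(f)
    if (length(f) >= 3L && nzchar(trimws(f[3L]))) trimws(f[3L]) else NA_character_,
    character(1))
  cat_name[is.na(cat_name)] <- cat_id[is.na(cat_name)]
  # first occurrence of each category fixes its name
  first <- !duplicated(cat_id)
  name_of <- cat_name[first]
  names(name_of) <- cat_id[first]
  conflicts <- unique(cat_id[cat_name != name_of[cat_id]])
  if (length(conflicts) > 0L)
    warning(sprintf("conflicting names for %d categor%s (first occurrence kept): %s",
                    length(conflicts), if (length(conflicts) == 1L) "y" else "ies",
                    paste(head(conflicts, 5L), collapse = ", ")), call. = FALSE)
  dup <- duplicated(paste0(gene, "\r", cat_id))
  entries <- data.frame(gene_id = gene[!dup], category_id = cat_id[!dup],
                        category_name = unname(name_of[cat_id[!dup]]),
                        stringsAsFactors = FALSE)
  new_annotation_table(entries,
                       report = list(raw_lines = parsed$raw_lines,
                                     collapsed_triples = nrow(entries),
                                     skipped = sum(!ok)))
}

new_annotation_table <- function(entries, report = list()) {
  structure(list(entries = entries, report = report),
            class = "annotation_table")
}

#' Read a query miRNA group
#'
#' One identifier per line, or a single comma-separated line. Lines starting
#' with `#` are ignored. Duplicates are collapsed (order-preserving) with a
#' warning.
#'
#' @param path Path to the query file.
#' @param case_fold Lower-case identifiers after trimming?
#' @return An object of class `query_group` with element `mirna_ids`.
#' @export
read_query <- function(path, case_fold = FALSE) {
  if (!file.exists(path)) ms_io_error(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L)
    ms_format_error(paste0("no miRNA identifiers in ", path))
  if (length(lines) == 1L && grepl(",", lines, fixed = TRUE))
    lines <- strsplit(lines, ",", fixed = TRUE)[[1L]]
  ids <- normalize_id(lines, case_fold)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    warning("duplicate miRNA identifiers in query collapsed", call. = FALSE)
    ids <- ids[!duplicated(ids)]
  }
  if (length(ids) == 0L)
    ms_format_error(paste0("no miRNA identifiers in ", path))
  query_group(ids)
}

#' Construct a query group from identifiers
#' @param mirna_ids Character vector of distinct miRNA identifiers.
#' @return An object of class `query_group`.
#' @export
query_group <- function(mirna_ids) {
  mirna_ids <- as.character(mirna_ids)
  if (anyDuplicated(mirna_ids)) mirna_ids <- mirna_ids[!duplicated(mirna_ids)]
  structure(list(mirna_ids = mirna_ids), class = "query_group")
}

# Fixed-decimal printing with 7 decimals: distinguishes 1/N at N = 1e6 and
# round-trips losslessly at every preset.
format_fraction <- function(x) {
  out <- rep("NA", length(x))
  out[!is.na(x)] <- sprintf("%.7f", x[!is.na(x)])
  out
}

#' Write an enrichment results table
#'
#' Writes a delimited text file with header columns `category_id`,
#' `category_name`, `category_size`, `overlap_count`, `overlap_proportion`,
#' `empirical_p_value`, `significance`, sorted by ascending empirical p-value
#' (excluded `NA` categories last) then category id. Significance is `""`,
#' `"*"` (FDR 0.05), `"**"` (FDR 0.01) or `"NA"` for categories excluded from
#' testing. The file is written to a temporary sibling and renamed on
#' success, so a fatal error never leaves a partial output.
#'
#' @param results Results data frame as produced by [run_enrichment()].
#' @param path Output path.
#' @param delimiter Field separator (default comma).
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, path, delimiter = ",") {
  results <- sort_results(results)
  header <- paste(c("category_id", "category_name", "category_size",
                    "overlap_count", "overlap_proportion",
                    "empirical_p_value", "significance"),
                  collapse = delimiter)
  sig <- results$significance
  sig[is.na(sig)] <- "NA"
  rows <- paste(results$category_id, results$category_name,
                results$category_size, results$overlap_count,
                format_fraction(results$overlap_proportion),
                format_fraction(results$empirical_p_value),
                sig, sep = delimiter)
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  ok <- tryCatch({
    writeLines(c(header, rows), tmp)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    ms_io_error(paste0("cannot write results to ", path))
  }
  invisible(path)
}

# Canonical row order: ascending p, NA (excluded) last, ties by category id.
sort_results <- function(results) {
  ord <- order(is.na(results$empirical_p_value), results$empirical_p_value,
               results$category_id, method = "radix")
  res <- results[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read back a results table written by [write_results()]
#'
#' @param path Path to the results file.
#' @param delimiter Field separator used when writing.
#' @return A data frame with the same columns as [run_enrichment()] results.
#' @export
read_results <- function(path, delimiter = ",") {
  if (!file.exists(path)) ms_io_error(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) ms_format_error(paste0("empty results file: ", path))
  fields <- strsplit(lines[-1L], delimiter, fixed = TRUE)
  get <- function(i) vapply(fields, `[`, character(1), i)
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  if (length(fields) == 0L) {
    return(data.frame(category_id = character(), category_name = character(),
                      category_size = integer(), overlap_count = integer(),
                      overlap_proportion = numeric(),
                      empirical_p_value = numeric(),
                      significance = character(), stringsAsFactors = FALSE))
  }
  # a trailing empty significance field is dropped by strsplit
  sig <- vapply(fields, function(f) if (length(f) >= 7L) f[7L] else "",
                character(1))
  sig[sig == "NA"] <- NA_character_
  data.frame(category_id = get(1L), category_name = get(2L),
             category_size = as.integer(get(3L)),
             overlap_count = as.integer(get(4L)),
             overlap_proportion = num(get(5L)),
             empirical_p_value = num(get(6L)),
             significance = sig, stringsAsFactors = FALSE)
}
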