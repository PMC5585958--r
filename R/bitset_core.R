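#' Build the gene universe
#'
#' The universe is a bijection between gene identifiers and 0-based bit
#' positions; it fixes the bitset width. Positions are assigned in sorted
#' (radix, locale-independent) gene-id order so bit assignment never depends
#' on input row order. Genes appearing only in the annotation table are
#' excluded by default: an untargetable gene can never contribute to an
#' overlap, so excluding it is semantics-preserving; set
#' `include_annotation_only_genes = TRUE` to index them anyway (this affects
#' the reported `category_size` denominator, not the p-values).
#'
#' @param interactions An `interaction_table`.
#' @param annotations Optionally an `annotation_table` (required when
#'   `include_annotation_only_genes = TRUE`).
#' @param include_annotation_only_genes Index genes seen only in annotations?
#' @return An object of class `gene_universe` with fields `gene_at`
#'   (character vector; position `i` holds the gene at bit `i - 1`),
#'   `index_of` (named integer vector of 0-based positions), `size` and
#'   `n_words`.
#' @export
build_universe <- function(interactions, annotations = NULL,
                           include_annotation_only_genes = FALSE) {
  if (nrow(interactions$entries) == 0L)
    ms_input_error("empty interaction table: cannot build a gene universe")
  genes <- interactions$entries$gene_id
  if (include_annotation_only_genes) {
    if (is.null(annotations))
      ms_input_error("annotations required to include annotation-only genes")
    genes <- c(genes, annotations$entries$gene_id)
  }
  gene_at <- radix_sort(unique(genes))
  index_of <- seq_along(gene_at) - 1L
  names(index_of) <- gene_at
  structure(list(gene_at = gene_at, index_of = index_of,
                 size = length(gene_at),
                 n_words = (length(gene_at) + 31L) %/% 32L),
            class = "gene_universe")
}

new_target_bitset <- function(words, width) {
  structure(unname(words), width = as.integer(width), class = "target_bitset")
}

#' Build a bitset from universe positions
#' @param positions Integer vector of 0-based bit positions (`< width`).
#' @param universe A `gene_universe` (fixes the width).
#' @return A `target_bitset`.
#' @export
target_bitset <- function(positions, universe) {
  positions <- as.integer(positions)
  if (length(positions) && (min(positions) < 0L || max(positions) >= universe$size))
    ms_logic_error("bit position outside the gene universe")
  new_target_bitset(bs_from_positions(positions, universe$n_words),
                    universe$size)
}

#' Bitset cardinality (population count)
#' @param bitset A `target_bitset`.
#' @return Integer number of set bits.
#' @export
bitset_cardinality <- function(bitset) bs_popcount(unclass(bitset))

#' Decode a bitset back to gene identifiers
#' @param bitset A `target_bitset`.
#' @param universe The `gene_universe` it was built over.
#' @return Character vector of gene ids, in bit-position order.
#' @export
bitset_genes <- function(bitset, universe) {
  universe$gene_at[bs_positions(unclass(bitset)) + 1L]
}

#' Per-miRNA target bitsets
#'
#' One fixed-width bitset per miRNA, holding its distinct predicted targets.
#' Bitsets are stored column-wise in a single integer matrix so the random
#' pool can be folded in one pass.
#'
#' @param interactions An `interaction_table`.
#' @param universe A `gene_universe` built from the same interaction table.
#' @return An object of class `mirna_bitset_map` with fields `words`
#'   (integer matrix, `n_words` x number of miRNAs, one column per miRNA in
#'   sorted id order), `mirna_ids` and `width`.
#' @export
mirna_bitsets <- function(interactions, universe) {
  mirna_ids <- radix_sort(unique(interactions$entries$mirna_id))
  pos <- universe$index_of[interactions$entries$gene_id]
  if (anyNA(pos))
    ms_logic_error("interaction gene absent from universe")
  by_mirna <- split(unname(pos), interactions$entries$mirna_id)[mirna_ids]
  words <- vapply(by_mirna, function(p) bs_from_positions(p, universe$n_words),
                  integer(universe$n_words))
  if (universe$n_words == 1L) words <- matrix(words, nrow = 1L,
                                              dimnames = list(NULL, mirna_ids))
  structure(list(words = words, mirna_ids = mirna_ids, width = universe$size),
            class = "mirna_bitset_map")
}

#' Extract one miRNA's bitset from a map
#' @param map A `mirna_bitset_map`.
#' @param mirna_id miRNA identifier.
#' @return A `target_bitset`.
#' @export
mirna_bitset <- function(map, mirna_id) {
  j <- match(mirna_id, map$mirna_ids)
  if (is.na(j)) ms_logic_error(paste0("no bitset for miRNA ", mirna_id))
  new_target_bitset(map$words[, j], map$width)
}

#' Union of member bitsets (bitwise-or fold)
#'
#' Folds the members into an initially all-zeros accumulator with
#' bitwise-or; the run's union counter (when supplied) is incremented by the
#' number of members folded.
#'
#' @param members List of `target_bitset`s of equal width.
#' @param width Bitset width, required only when `members` is empty.
#' @param counters Optional counter environment from a run.
#' @return A `target_bitset`.
#' @export
group_union <- function(members, width = NULL, counters = NULL) {
  if (length(members) == 0L) {
    if (is.null(width)) ms_logic_error("empty member list and no width given")
    warning("union of an empty member list is the empty set", call. = FALSE)
    return(new_target_bitset(integer((width + 31L) %/% 32L), width))
  }
  widths <- vapply(members, function(m) as.integer(attr(m, "width")),
                   integer(1))
  if (length(unique(widths)) != 1L)
    ms_logic_error("bitset width mismatch in group_union")
  acc <- integer(length(unclass(members[[1L]])))
  for (m in members) acc <- bs_or(acc, unclass(m))
  if (!is.null(counters)) counters$unions <- counters$unions + length(members)
  new_target_bitset(acc, widths[1L])
}

#' Build category indexes over a universe
#'
#' Maps each annotation category to the sorted 0-based bit positions of its
#' member genes that are present in the universe. Categories left empty after
#' universe filtering are dropped (listed in the `dropped` attribute); the
#' pre-filter gene count is retained per category as `size_prefilter`.
#'
#' @param annotations An `annotation_table`.
#' @param universe A `gene_universe`.
#' @return A list of class `category_index_list`; each element has fields
#'   `category_id`, `name`, `gene_bits` (strictly increasing 0-based
#'   positions), `size` and `size_prefilter`.
#' @export
build_category_index <- function(annotations, universe) {
  ent <- annotations$entries
  cat_ids <- radix_sort(unique(ent$category_id))
  name_of <- ent$category_name[!duplicated(ent$category_id)]
  names(name_of) <- ent$category_id[!duplicated(ent$category_id)]
  by_cat <- split(ent$gene_id, ent$category_id)[cat_ids]
  out <- lapply(cat_ids, function(cid) {
    genes <- by_cat[[cid]]
    pos <- universe$index_of[genes]
    pos <- sort(unname(pos[!is.na(pos)]))
    list(category_id = cid, name = unname(name_of[cid]), gene_bits = pos,
         size = length(pos), size_prefilter = length(genes))
  })
  keep <- vapply(out, function(x) x$size > 0L, logical(1))
  dropped <- cat_ids[!keep]
  structure(out[keep], dropped = dropped, class = "category_index_list")
}

#' Overlap size by bit-probing
#'
#' For each gene in the category, the corresponding bit of the group bitset
#' is examined; a counter is incremented for every set bit. The run's probe
#' counter (when supplied) is incremented by the category size.
#'
#' @param group A `target_bitset` (a miRNA group's union of targets).
#' @param category A category index element from [build_category_index()].
#' @param counters Optional counter environment.
#' @return Integer intersection size, between 0 and `category$size`.
#' @export
probe_overlap <- function(group, category, counters = NULL) {
  if (length(category$gene_bits) &&
      max(category$gene_bits) >= attr(group, "width"))
    ms_logic_error("category position outside the group bitset width")
  if (!is.null(counters)) counters$probes <- counters$probes + category$size
  bs_probe(unclass(group), category$gene_bits)
}

#' Overlap size by bitwise-and + popcount
#'
#' Cross-check implementation of the intersection size: popcount of the
#' bitwise-and of two equal-width bitsets. Used in tests as the oracle for
#' [probe_overlap()].
#'
#' @param group,category_bitset Equal-width `target_bitset`s.
#' @return Integer intersection size.
#' @export
popcount_overlap <- function(group, category_bitset) {
  if (as.integer(attr(group, "width")) !=
      as.integer(attr(category_bitset, "width")))
    ms_logic_error("bitset width mismatch in popcount_overlap")
  bs_and_popcount(unclass(group), unclass(category_bitset))
}
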