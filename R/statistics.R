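#' Benjamini-Hochberg significance marking
#'
#' Standard BH step-up over the `m` tested (non-`NA`) p-values, run at each
#' of the two FDR levels: categories significant at `alpha2` are marked
#' `"**"`, those significant at `alpha1` only are marked `"*"`, the rest
#' `""`. Excluded (`NA`) categories keep `NA` significance and do not count
#' toward `m`. Marks are nested by construction (`"**"` implies significance
#' at `alpha1`), ties at the threshold rank all receive the mark, and the
#' marking depends only on the multiset of p-values, not on input order.
#'
#' @param results Data frame with an `empirical_p_value` column (other
#'   columns preserved), or a bare numeric p-value vector.
#' @param alpha_levels `(alpha1, alpha2)` with `alpha2 < alpha1`.
#' @return List of class `marked_results` with `results` (the input with a
#'   `significance` column) and `m` (number of tested categories). For a
#'   bare vector input, `results` is a data frame with columns
#'   `empirical_p_value` and `significance`.
#' @export
bh_mark <- function(results, alpha_levels = c(0.05, 0.01)) {
  if (is.numeric(results))
    results <- data.frame(empirical_p_value = results)
  p <- results$empirical_p_value
  if (any(p < 0 | p > 1, na.rm = TRUE))
    ms_input_error("p-values must lie in [0, 1]")
  tested <- !is.na(p)
  m <- sum(tested)
  sig <- rep(NA_character_, length(p))
  if (m > 0L) {
    adj <- p.adjust(p[tested], method = "BH")
    marks <- ifelse(adj <= alpha_levels[2L], "**",
                    ifelse(adj <= alpha_levels[1L], "*", ""))
    sig[tested] <- marks
  }
  results$significance <- sig
  structure(list(results = results, m = m), class = "marked_results")
}

#' One-sided hypergeometric (Fisher) over-representation p-value
#'
#' The classic gene-level comparator the empirical method replaces:
#' `P[X >= overlap]` for `X` hypergeometric with population `universe_size`,
#' `category$size` successes and `cardinality(query_targets)` draws. Biased
#' for miRNA-group questions because the union of a random miRNA group is
#' not a uniform random gene set.
#'
#' @param query_targets The query group's union `target_bitset`.
#' @param category A category index element from [build_category_index()].
#' @param universe_size Number of genes in the universe.
#' @return P-value in (0, 1].
#' @export
hypergeom_pvalue <- function(query_targets, category, universe_size) {
  n_draws <- bitset_cardinality(query_targets)
  if (universe_size < n_draws || category$size > universe_size)
    ms_input_error("hypergeometric parameters exceed the universe size")
  k <- probe_overlap(query_targets, category)
  phyper(k - 1L, category$size, universe_size - category$size, n_draws,
         lower.tail = FALSE)
}
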