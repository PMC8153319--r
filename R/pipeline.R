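#' Full reference-gene stability analysis
#'
#' Convenience driver running the complete evaluation on one Ct table:
#' replicate collapsing, per-tissue summary with Ct-range screening, geNorm
#' (ranking + optimal gene number), NormFinder, BestKeeper, and the
#' geometric-mean rank consensus with the recommended best combination.
#'
#' @param ct a \code{\link{ct_table}}.
#' @param base amplification base for the quantity transform (default 2).
#' @param collapse collapse replicates to tissue means (default TRUE).
#' @param v_threshold geNorm pairwise-variation cut-off (default 0.15).
#' @param range_threshold Ct-range screening threshold, cycles (default 4).
#' @param index_batch_size BestKeeper index batching (see
#'   \code{\link{bestkeeper}}); NULL for a single all-gene index.
#' @param sd_cutoff BestKeeper SD cut-off, cycles (default 1).
#' @param r_digits BestKeeper r display-precision ranking (see
#'   \code{\link{bestkeeper}}).
#' @param groups optional sample grouping for NormFinder (replicate-level
#'   runs); default ungrouped.
#' @return list with components \code{summary} (tissue_summary),
#'   \code{range_flagged}, \code{genorm}, \code{normfinder},
#'   \code{bestkeeper}, \code{consensus}, \code{optimal_n} and
#'   \code{best_combination}.
#' @export
stability_analysis <- function(ct, base = 2, collapse = TRUE,
                               v_threshold = 0.15, range_threshold = 4,
                               index_batch_size = NULL, sd_cutoff = 1,
                               r_digits = NULL, groups = NULL) {
  stopifnot(inherits(ct, "ct_table"))
  summ <- tissue_summary(ct)
  m <- ct_matrix(ct, collapse = collapse)
  q <- to_quantities(m, base = base)
  gn <- genorm(q, v_threshold = v_threshold)
  nf <- normfinder(q, groups = groups)
  bk <- bestkeeper(m, index_batch_size = index_batch_size,
                   sd_cutoff = sd_cutoff, r_digits = r_digits)
  genes <- rownames(m)
  cons <- consensus_rank(data.frame(
    gene = genes,
    genorm = unname(gn$rank_of[genes]),
    normfinder = unname(nf$rank_of[genes]),
    bestkeeper = unname(bk$rank_of[genes]),
    stringsAsFactors = FALSE))
  n_opt <- if (is.na(gn$optimal_n)) 2L else gn$optimal_n
  list(summary = summ,
       range_flagged = flag_unstable_by_range(summ, range_threshold),
       genorm = gn, normfinder = nf, bestkeeper = bk, consensus = cons,
       optimal_n = gn$optimal_n,
       best_combination = select_combination(cons, min(n_opt, length(genes))))
}
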