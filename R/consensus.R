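#' Geometric-mean rank consensus across stability methods
#'
#' Integrates per-method stability ranks (typically geNorm, NormFinder and
#' BestKeeper) into one comprehensive ranking: each gene's consensus score is
#' the geometric mean of its method ranks, and the combined ranking orders
#' genes by ascending score. Input ranks may contain ties (geNorm assigns
#' rank 1 to both of its final genes); they enter the product as-is.
#'
#' @param method_ranks data frame with a \code{gene} column and one numeric
#'   rank column per method, or a named genes-by-methods matrix. Every gene
#'   needs a rank from every method.
#' @return object of class \code{consensus_ranking}: data frame with gene,
#'   the method ranks, \code{geo_mean_rank} and \code{combined_rank} (a
#'   permutation of 1..k; ties in the geometric mean are broken by the best
#'   single-method rank, then by gene name).
#' @examples
#' consensus_rank(data.frame(gene = c("A", "B"), m1 = c(1, 2), m2 = c(2, 1),
#'                           m3 = c(1, 2)))
#' @export
consensus_rank <- function(method_ranks) {
  df <- as.data.frame(method_ranks)
  if (!"gene" %in% names(df)) {
    if (is.null(rownames(method_ranks)))
      stop("method_ranks needs a 'gene' column or row names")
    df <- cbind(gene = rownames(method_ranks), df)
  }
  rank_cols <- setdiff(names(df), "gene")
  if (length(rank_cols) < 1) stop("no method rank columns")
  ranks <- as.matrix(df[rank_cols])
  if (anyNA(ranks))
    stop("missing method rank for gene(s): ",
         paste(df$gene[apply(ranks, 1, anyNA)], collapse = ", "))
  if (any(ranks < 1)) stop("ranks must be >= 1")
  df$geo_mean_rank <- apply(ranks, 1, geometric_mean)
  best <- apply(ranks, 1, min)
  ord <- order(df$geo_mean_rank, best, df$gene)
  df$combined_rank <- match(seq_len(nrow(df)), ord)
  structure(df, class = c("consensus_ranking", "data.frame"))
}

#' Best reference-gene combination
#'
#' The recommended combination is the top n genes of the combined ranking,
#' where n is the optimal gene number from geNorm's pairwise-variation rule.
#'
#' @param consensus a \code{\link{consensus_rank}} result.
#' @param n number of genes (e.g. \code{genorm(...)$optimal_n}).
#' @return character vector of n gene names, best first.
#' @export
select_combination <- function(consensus, n) {
  stopifnot(inherits(consensus, "consensus_ranking"))
  n <- as.integer(n)
  if (n < 1 || n > nrow(consensus)) stop("n out of range")
  consensus$gene[order(consensus$combined_rank)][seq_len(n)]
}

#' Tissue-specific reference-gene pair
#'
#' Within one tissue, restrict to genes whose within-tissue mean Ct lies in a
#' moderate-expression window (closed bounds, default [20, 25] cycles) and
#' pick the two with the smallest within-tissue SD. Ties are broken by the
#' smaller distance of the mean to the window midpoint, then by gene name.
#'
#' @param summary a \code{\link{tissue_summary}} whose cells carry
#'   within-tissue SDs.
#' @param tissue tissue label to select for.
#' @param window closed Ct window, length-2 numeric (low, high).
#' @return list with \code{tissue}, \code{pair} (two gene names, most stable
#'   first), \code{window} and \code{candidates} (the eligible genes with
#'   their means and SDs).
#' @export
select_tissue_pair <- function(summary, tissue, window = c(20, 25)) {
  stopifnot(inherits(summary, "tissue_summary"),
            length(window) == 2, window[1] < window[2])
  cells <- summary$cells[summary$cells$tissue == tissue, ]
  if (nrow(cells) == 0) stop("unknown tissue: ", tissue)
  if (anyNA(cells$sd_ct))
    stop("within-tissue SDs unavailable (single replicate?)")
  eligible <- cells[cells$mean_ct >= window[1] & cells$mean_ct <= window[2], ]
  if (nrow(eligible) < 2)
    stop("fewer than 2 genes with mean Ct inside [", window[1], ", ",
         window[2], "] in tissue ", tissue)
  mid <- mean(window)
  ord <- order(eligible$sd_ct, abs(eligible$mean_ct - mid), eligible$gene)
  eligible <- eligible[ord, ]
  list(tissue = tissue, pair = eligible$gene[1:2], window = window,
       candidates = eligible[c("gene", "mean_ct", "sd_ct")])
}

#' Write a consensus ranking as TSV
#'
#' @param consensus a \code{\link{consensus_rank}} result.
#' @param file output path. Geometric-mean ranks are written rounded to two
#'   decimals (display convention); combined ranks use full precision.
#' @export
write_consensus <- function(consensus, file) {
  out <- as.data.frame(consensus)
  out$geo_mean_rank <- round(out$geo_mean_rank, 2)
  out <- out[order(out$combined_rank), ]
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
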