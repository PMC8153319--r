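#' BestKeeper descriptive statistics, index correlation and ranking
#'
#' BestKeeper works on the raw Ct scale. Per gene it reports the geometric
#' and arithmetic mean Ct, min, max, the dispersion \code{SD} — defined, as
#' in the original tool, as the \emph{mean absolute deviation} around the
#' arithmetic mean, not the n - 1 standard deviation — and
#' \code{CV = 100 * SD / mean}. The BestKeeper index is the per-sample
#' geometric mean of the candidate genes' Ct values, and each gene's \code{r}
#' is its Pearson correlation with that index (two-sided p from the t
#' distribution with n - 2 df). A gene with SD > 1 cycle is conventionally
#' considered unstable regardless of its r.
#'
#' The ranking reflects that convention: genes with \code{SD <= sd_cutoff}
#' come first, ordered by descending r (ties: smaller SD, then name);
#' genes above the cut-off follow, ordered by ascending SD. A zero-variance
#' gene has undefined r and is ranked last within its SD class.
#'
#' @param ct a \code{\link{ct_table}} or genes-by-samples Ct matrix (tissue
#'   means by default, see \code{\link{ct_matrix}}); all Ct > 0, >= 2 samples.
#' @param index_genes genes used to build the index (default: all).
#' @param index_batch_size optionally split the panel, in input order, into
#'   consecutive batches of at most this many genes, each gene being
#'   correlated with its own batch's index. The original spreadsheet tool
#'   capped a run at 10 genes, so published panels larger than that were
#'   processed in such batches; set 10 to reproduce them. Default NULL (one
#'   index from all \code{index_genes}).
#' @param sd_cutoff cycles; boundary of the stable / unstable ranking classes
#'   (default 1).
#' @param r_digits optionally round r to this many digits before ranking.
#'   The spreadsheet tool displays r to 3 decimals and published rankings
#'   were read off that display, so \code{r_digits = 3} (with the SD
#'   tie-break) reproduces them; default NULL ranks at full precision.
#' @return object of class \code{bestkeeper}: \code{table} (data frame with
#'   gene, geo_mean, arith_mean, min_ct, max_ct, sd_mad, cv_percent, r,
#'   p_value), \code{index} (per-sample; a list of per-batch indices when
#'   batched), \code{rank_of}.
#' @export
bestkeeper <- function(ct, index_genes = NULL, index_batch_size = NULL,
                       sd_cutoff = 1, r_digits = NULL) {
  m <- if (inherits(ct, "ct_table")) ct_matrix(ct) else as.matrix(ct)
  if (anyNA(m)) stop("incomplete Ct matrix")
  if (any(m <= 0)) stop("all Ct values must be positive")
  if (ncol(m) < 2) stop("need at least 2 samples")

  arith <- rowMeans(m)
  tab <- data.frame(
    gene = rownames(m),
    geo_mean = apply(m, 1, geometric_mean),
    arith_mean = arith,
    min_ct = apply(m, 1, min),
    max_ct = apply(m, 1, max),
    sd_mad = rowMeans(abs(m - arith)),
    cv_percent = 100 * rowMeans(abs(m - arith)) / arith,
    stringsAsFactors = FALSE, row.names = NULL
  )

  index_genes <- index_genes %||% rownames(m)
  if (!all(index_genes %in% rownames(m))) stop("unknown index gene(s)")
  if (length(index_genes) == 0) stop("empty index gene set")
  batches <- if (is.null(index_batch_size)) list(index_genes)
             else split(index_genes,
                        ceiling(seq_along(index_genes) / index_batch_size))
  index <- lapply(batches, function(g)
    col_geometric_mean(m[g, , drop = FALSE]))

  tab$r <- NA_real_
  tab$p_value <- NA_real_
  for (b in seq_along(batches)) {
    # genes outside every batch are correlated with the first (full) index
    in_batch <- if (length(batches) == 1) rownames(m) else batches[[b]]
    if (stats::sd(index[[b]]) == 0) next
    for (g in in_batch) {
      gv <- m[g, ]
      if (stats::sd(gv) == 0) next  # r undefined, stays NA
      if (ncol(m) >= 3) {
        ht <- stats::cor.test(gv, index[[b]])
        tab$r[tab$gene == g] <- unname(ht$estimate)
        tab$p_value[tab$gene == g] <- ht$p.value
      } else {
        tab$r[tab$gene == g] <- stats::cor(gv, index[[b]])
      }
    }
  }

  structure(list(table = tab,
                 index = if (length(index) == 1) index[[1]] else index,
                 rank_of = bestkeeper_rank(tab, sd_cutoff, r_digits),
                 sd_cutoff = sd_cutoff),
            class = "bestkeeper")
}

# Composite ranking: SD <= cutoff by descending r (NA r last; ties by smaller
# SD then name), then SD > cutoff by ascending SD (ties by name).
bestkeeper_rank <- function(tab, sd_cutoff, r_digits = NULL) {
  lo <- tab[tab$sd_mad <= sd_cutoff, ]
  hi <- tab[tab$sd_mad > sd_cutoff, ]
  r_key <- ifelse(is.na(lo$r), -Inf, lo$r)
  if (!is.null(r_digits)) r_key <- round(r_key, r_digits)
  lo_order <- lo$gene[order(-r_key, lo$sd_mad, lo$gene)]
  hi_order <- hi$gene[order(hi$sd_mad, hi$gene)]
  ordering <- c(lo_order, hi_order)
  stats::setNames(seq_along(ordering), ordering)[tab$gene]
}

#' Per-sample BestKeeper index
#'
#' Geometric mean, per sample, of the Ct values of the given genes.
#'
#' @param ct \code{\link{ct_table}} or Ct matrix.
#' @param genes subset of genes (default all, non-empty).
#' @return named numeric vector, one value per sample (cycles).
#' @export
bestkeeper_index <- function(ct, genes = NULL) {
  m <- if (inherits(ct, "ct_table")) ct_matrix(ct) else as.matrix(ct)
  genes <- genes %||% rownames(m)
  if (length(genes) == 0) stop("empty gene subset")
  if (!all(genes %in% rownames(m))) stop("unknown gene(s)")
  col_geometric_mean(m[genes, , drop = FALSE])
}

#' @export
print.bestkeeper <- function(x, ...) {
  tab <- x$table
  tab <- tab[order(x$rank_of[tab$gene]), ]
  print(cbind(tab[1], round(tab[-1], 3), rank = x$rank_of[tab$gene]),
        row.names = FALSE)
  invisible(x)
}

#' Write the BestKeeper table as TSV
#'
#' Columns mirror the conventional published layout: Geometric Mean, Average
#' Mean, Minimum, Maximum, SD, CV, r, p-Value.
#'
#' @param x a \code{\link{bestkeeper}} result.
#' @param file output path.
#' @export
write_bestkeeper <- function(x, file) {
  tab <- x$table
  out <- data.frame(Gene = tab$gene,
                    `Geometric Mean` = round(tab$geo_mean, 2),
                    `Average Mean` = round(tab$arith_mean, 2),
                    Minimum = round(tab$min_ct, 2),
                    Maximum = round(tab$max_ct, 2),
                    SD = round(tab$sd_mad, 2),
                    CV = round(tab$cv_percent, 2),
                    r = round(tab$r, 3),
                    `p-Value` = round(tab$p_value, 3),
                    check.names = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
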