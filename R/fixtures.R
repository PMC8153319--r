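#' Published tissue-level Ct panel for Schima superba
#'
#' The package ships the published per-tissue mean Ct table for a panel of 19
#' candidate reference genes assayed in six tissues (leaf, bud, fruit,
#' phloem, root, xylem) of \emph{Schima superba}, together with the printed
#' within-tissue standard deviations (n = 3 biological replicates). The
#' replicate-level measurements were never deposited, so the tissue means are
#' the analysis-ready input: the original stability programs demonstrably ran
#' on these six values per gene.
#'
#' @return \code{schima_ct()} returns a \code{\link{ct_table}} with 114
#'   records (19 genes x 6 tissues, one collapsed value each);
#'   \code{schima_tissue_summary()} returns the corresponding
#'   \code{\link{tissue_summary}} carrying the published within-tissue SDs;
#'   \code{schima_method_ranks()} returns the published per-method stability
#'   ranks (geNorm, NormFinder, BestKeeper) for the same panel, with the
#'   published geometric-mean and combined ranking columns alongside for
#'   reference.
#' @name schima
NULL

schima_file <- function(name) {
  system.file("extdata", name, package = "refstab", mustWork = TRUE)
}

#' @rdname schima
#' @export
schima_ct <- function() {
  tab <- utils::read.delim(schima_file("schima_ct_tissue_means.tsv"),
                           stringsAsFactors = FALSE)
  ct_table(data.frame(gene = tab$gene, sample = tab$tissue,
                      tissue = tab$tissue, replicate = 1L, ct = tab$mean_ct,
                      stringsAsFactors = FALSE))
}

#' @rdname schima
#' @export
schima_tissue_summary <- function() {
  tab <- utils::read.delim(schima_file("schima_ct_tissue_means.tsv"),
                           stringsAsFactors = FALSE)
  new_tissue_summary(data.frame(gene = tab$gene, tissue = tab$tissue,
                                mean_ct = tab$mean_ct, sd_ct = tab$sd_ct,
                                n = tab$n, stringsAsFactors = FALSE))
}

#' @rdname schima
#' @export
schima_method_ranks <- function() {
  utils::read.delim(schima_file("schima_method_ranks.tsv"),
                    stringsAsFactors = FALSE)
}
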