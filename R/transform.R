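#' Convert Ct values to relative quantities
#'
#' Converts a Ct matrix to the relative quantities consumed by geNorm and
#' NormFinder: for gene i and sample j,
#' \code{q_ij = base^-(Ct_ij - min_j Ct_ij)}, so each gene's most-expressed
#' (lowest-Ct) sample is anchored at exactly 1 and all quantities lie in
#' (0, 1]. With the default base 2 this is the classical 2^-dCt transform;
#' an efficiency-corrected run uses per-gene \code{base = 1 + E}.
#'
#' The anchor is a per-gene scaling only: both geNorm and NormFinder are
#' invariant to per-gene rescaling, so any other anchor gives identical
#' stability results.
#'
#' @param x a \code{\link{ct_table}} or a genes-by-samples numeric matrix.
#' @param base amplification factor per cycle; scalar or per-gene vector
#'   (recycled/matched by gene name). Must exceed 1. Default 2.
#' @param collapse when \code{x} is a \code{ct_table}, collapse replicates to
#'   tissue means first (default TRUE, see \code{\link{ct_matrix}}).
#' @return object of class \code{quantity_matrix}: list with \code{q}
#'   (genes x samples matrix), \code{log2_q} and \code{base}.
#' @examples
#' q <- to_quantities(matrix(c(20, 21, 22), 1, dimnames = list("g", NULL)))
#' q$q  # 1, 0.5, 0.25
#' @export
to_quantities <- function(x, base = 2, collapse = TRUE) {
  m <- if (inherits(x, "ct_table")) ct_matrix(x, collapse = collapse) else as.matrix(x)
  if (anyNA(m)) stop("incomplete Ct matrix")
  if (is.null(rownames(m))) rownames(m) <- paste0("gene", seq_len(nrow(m)))
  if (length(base) == 1) base <- rep(base, nrow(m))
  if (!is.null(names(base))) base <- base[rownames(m)]
  if (length(base) != nrow(m) || any(is.na(base)))
    stop("base must be scalar or one value per gene")
  if (any(base <= 1)) stop("amplification base must exceed 1")
  dct <- m - apply(m, 1, min)
  log2q <- -sweep(dct, 1, log2(base), `*`)
  q <- 2^log2q
  structure(list(q = q, log2_q = log2q, base = base),
            class = "quantity_matrix")
}

#' Log2 relative quantities
#'
#' Convenience wrapper returning the genes-by-samples matrix of log2 relative
#' quantities, i.e. \code{-dCt * log2(base)} (just \code{-dCt} for base 2).
#' NormFinder operates on this scale.
#'
#' @inheritParams to_quantities
#' @return numeric matrix of log2 quantities (all <= 0, per-gene max 0).
#' @export
to_log_quantities <- function(x, base = 2, collapse = TRUE) {
  to_quantities(x, base = base, collapse = collapse)$log2_q
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat("Relative quantity matrix:", nrow(x$q), "genes x", ncol(x$q),
      "samples (base",
      if (length(unique(x$base)) == 1) format(x$base[1]) else "per-gene", ")\n")
  invisible(x)
}
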