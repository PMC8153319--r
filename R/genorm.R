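#' geNorm pairwise variation between two genes
#'
#' \code{V_jk} is the sample standard deviation (n - 1 denominator), over
#' samples, of the log2 ratio of the two genes' relative quantities. Two
#' ideal reference genes hold a constant expression ratio across samples, so
#' \code{V_jk = 0}; noise in either gene inflates it.
#'
#' @param q a \code{\link{to_quantities}} result or genes-by-samples quantity
#'   matrix.
#' @param gene_j,gene_k gene names or row indices; must differ.
#' @return the pairwise variation in log2 units.
#' @export
pairwise_variation <- function(q, gene_j, gene_k) {
  m <- quantity_mat(q)
  if (ncol(m) < 2) stop("need at least 2 samples")
  j <- resolve_gene(m, gene_j); k <- resolve_gene(m, gene_k)
  if (j == k) stop("gene_j and gene_k must differ")
  stats::sd(log2(m[j, ] / m[k, ]))
}

quantity_mat <- function(q) {
  if (inherits(q, "quantity_matrix")) q$q else as.matrix(q)
}

resolve_gene <- function(m, g) {
  i <- if (is.character(g)) match(g, rownames(m)) else as.integer(g)
  if (is.na(i) || i < 1 || i > nrow(m)) stop("unknown gene: ", g)
  i
}

#' geNorm expression stability M
#'
#' \code{M_j} is the arithmetic mean of the pairwise variations \code{V_jk}
#' of gene j against every other candidate in the subset. Smaller M means
#' more stable expression relative to the panel.
#'
#' @param q quantities (see \code{\link{pairwise_variation}}).
#' @param genes subset of gene names to evaluate (default: all, size >= 2).
#' @return named numeric vector of M values.
#' @details Internally the pairwise variations are read off the covariance
#'   matrix of the log2 quantities
#'   (\code{var(y_j - y_k) = C_jj + C_kk - 2 C_jk}), which keeps the
#'   iterative exclusion of \code{\link{genorm}} O(k^2) per step.
#' @export
genorm_m <- function(q, genes = NULL) {
  m <- quantity_mat(q)
  if (ncol(m) < 2) stop("need at least 2 samples")
  y <- log2(m)
  genes <- genes %||% rownames(y)
  if (length(genes) < 2) stop("need at least 2 genes")
  y <- y[genes, , drop = FALSE]
  C <- stats::cov(t(y))
  vjk <- sqrt(pmax(outer(diag(C), diag(C), `+`) - 2 * C, 0))
  M <- rowSums(vjk) / (nrow(y) - 1)
  names(M) <- genes
  M
}

#' geNorm stability ranking, V series and optimal gene number
#'
#' Runs the full geNorm procedure: repeatedly compute M over the remaining
#' genes and exclude the single least stable (highest M) gene until two
#' remain. The two survivors share rank 1; the gene removed last gets rank 2,
#' and so on (dense ranks 1..k-1 over k genes). The normalization factor
#' \code{NF_n} is the per-sample geometric mean of the top-n genes'
#' quantities in ranking order, and the pairwise variation
#' \code{V_n/n+1 = sd(log2(NF_n / NF_n+1))} measures what the (n+1)-th gene
#' adds; the optimal number of reference genes is the smallest n with
#' \code{V_n/n+1 < threshold} (default 0.15).
#'
#' @param q quantities from \code{\link{to_quantities}} (or a quantity
#'   matrix); at least 3 genes.
#' @param v_threshold pairwise-variation cut-off for the optimal gene number.
#' @return object of class \code{genorm}: \code{ranking} (genes, most stable
#'   first; the first two are tied), \code{rank_of} (named dense ranks),
#'   \code{m_trajectory} (list of M vectors per exclusion step),
#'   \code{v_series} (data frame n, v), \code{optimal_n} and
#'   \code{optimal_n_capped} (TRUE when no V fell below the threshold and
#'   the full panel size is returned).
#' @details Ties in the maximal M are broken by excluding the
#'   lexicographically last gene name; exact ties have measure zero on real
#'   data. The V series requires at least 4 genes and is skipped (with
#'   \code{optimal_n = NA}) below that.
#' @export
genorm <- function(q, v_threshold = 0.15) {
  qm <- quantity_mat(q)
  k <- nrow(qm)
  if (k < 3) stop("geNorm ranking needs at least 3 genes")
  remaining <- rownames(qm)
  removed <- character(0)
  trajectory <- list()
  while (length(remaining) > 2) {
    M <- genorm_m(qm, remaining)
    trajectory[[length(trajectory) + 1L]] <- M
    worst <- names(M)[M == max(M)]
    worst <- sort(worst)[length(worst)]   # lexicographically last on ties
    removed <- c(removed, worst)
    remaining <- setdiff(remaining, worst)
  }
  trajectory[[length(trajectory) + 1L]] <- genorm_m(qm, remaining)
  ranking <- c(sort(remaining), rev(removed))
  rank_of <- stats::setNames(c(1L, 1L, seq(2L, length.out = length(removed))),
                             ranking)

  v_series <- NULL
  optimal_n <- NA_integer_
  capped <- FALSE
  if (k >= 4) {
    v <- vapply(2:(k - 1), function(n) {
      nf_n <- normalization_factor(qm, ranking[seq_len(n)])
      nf_n1 <- normalization_factor(qm, ranking[seq_len(n + 1)])
      stats::sd(log2(nf_n / nf_n1))
    }, numeric(1))
    v_series <- data.frame(n = 2:(k - 1), v = v)
    below <- which(v < v_threshold)
    if (length(below)) {
      optimal_n <- v_series$n[below[1]]
    } else {
      optimal_n <- k
      capped <- TRUE
    }
  }
  structure(list(ranking = ranking, rank_of = rank_of,
                 m_trajectory = trajectory, v_series = v_series,
                 optimal_n = optimal_n, optimal_n_capped = capped,
                 v_threshold = v_threshold),
            class = "genorm")
}

#' Per-sample normalization factor from a set of reference genes
#'
#' The geNorm normalization factor \code{NF_n} for a sample is the geometric
#' mean of the n reference genes' relative quantities in that sample.
#'
#' @param q quantities.
#' @param genes at least two gene names (or indices).
#' @return named numeric vector, one NF per sample.
#' @export
normalization_factor <- function(q, genes) {
  m <- quantity_mat(q)
  if (length(genes) < 2) stop("normalization factor needs at least 2 genes")
  idx <- vapply(genes, function(g) resolve_gene(m, g), integer(1))
  col_geometric_mean(m[idx, , drop = FALSE])
}

#' @export
print.genorm <- function(x, ...) {
  cat("geNorm ranking (most stable first):\n")
  cat(" ", paste(x$ranking, collapse = " > "), "\n")
  if (!is.null(x$v_series))
    cat("optimal number of reference genes:", x$optimal_n,
        if (x$optimal_n_capped) "(no V below threshold)" else "", "\n")
  invisible(x)
}
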