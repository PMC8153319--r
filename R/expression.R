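#' Relative expression by the delta-delta-Ct method
#'
#' Normalizes a target gene against one or more reference genes and a
#' calibrator sample: \code{dCt(sample) = Ct_target - R(sample)} where R is
#' the arithmetic mean of the reference genes' Ct values in that sample
#' (averaging on the Ct scale equals a geometric-mean normalization factor on
#' the linear scale); \code{ddCt = dCt(sample) - dCt(calibrator)}; relative
#' expression \code{= base^-ddCt}, 1 at the calibrator by construction.
#'
#' @param ct a \code{\link{ct_table}} (replicates collapsed to tissue level
#'   by default).
#' @param target target gene name (must not be a reference).
#' @param references character vector of reference gene names.
#' @param calibrator sample the fold changes are anchored to; defaults to the
#'   sample with the smallest dCt (highest relative target expression), so
#'   all fold changes are <= 1.
#' @param base amplification base (default 2); a per-gene named vector
#'   enables efficiency-corrected quantification with \code{base = 1 + E}.
#' @param collapse collapse replicates to tissue means first (default TRUE).
#' @return data frame of class \code{relative_expression} with columns
#'   \code{sample}, \code{rel_expr}; attributes \code{calibrator},
#'   \code{references}, \code{target}.
#' @export
relative_expression <- function(ct, target, references, calibrator = NULL,
                                base = 2, collapse = TRUE) {
  m <- if (inherits(ct, "ct_table")) ct_matrix(ct, collapse = collapse)
       else as.matrix(ct)
  if (anyNA(m)) stop("incomplete Ct matrix")
  if (target %in% references) stop("target must not be among the references")
  missing_g <- setdiff(c(target, references), rownames(m))
  if (length(missing_g)) stop("unknown gene(s): ", paste(missing_g, collapse = ", "))

  if (length(base) == 1) {
    log2base <- stats::setNames(rep(log2(base), nrow(m)), rownames(m))
  } else {
    log2base <- log2(base[rownames(m)])
    if (anyNA(log2base)) stop("base must cover every gene")
  }
  # work on the efficiency-weighted log scale so per-gene bases are honoured:
  # base_i^-Ct equals 2^-(Ct * log2 base_i)
  w <- sweep(m, 1, log2base[rownames(m)], `*`)
  dct <- w[target, ] - colMeans(w[references, , drop = FALSE])

  if (is.null(calibrator)) calibrator <- names(which.min(dct))
  if (!calibrator %in% colnames(m)) stop("unknown calibrator: ", calibrator)
  rel <- 2^-(dct - dct[calibrator])
  out <- data.frame(sample = colnames(m), rel_expr = unname(rel),
                    stringsAsFactors = FALSE)
  attr(out, "calibrator") <- calibrator
  attr(out, "references") <- references
  attr(out, "target") <- target
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' Compare expression profiles across reference-gene sets
#'
#' Computes the target's relative expression under each candidate reference
#' set and measures cross-set concordance as the Spearman correlation of the
#' per-sample profiles. Each set is scored against the element-wise median
#' log2 profile across all sets (a majority consensus, robust to a minority
#' of discordant sets); a set whose score falls below \code{flag_threshold}
#' is flagged as giving a discordant normalization (the behaviour expected
#' of an unstable reference).
#'
#' @inheritParams relative_expression
#' @param reference_sets list of >= 2 character vectors of reference genes.
#' @param flag_threshold minimum Spearman correlation with the consensus of
#'   the other sets (default 0.8).
#' @return list with \code{profiles} (samples x sets matrix of relative
#'   expression), \code{concordance} (sets x sets Spearman matrix, unit
#'   diagonal), \code{consensus_score} (per set) and \code{flagged} (set
#'   names below the threshold).
#' @export
expression_profile <- function(ct, target, reference_sets, calibrator = NULL,
                               base = 2, collapse = TRUE,
                               flag_threshold = 0.8) {
  if (length(reference_sets) < 2) stop("need at least 2 reference sets")
  if (is.null(names(reference_sets)))
    names(reference_sets) <- vapply(reference_sets, paste, "", collapse = "+")
  profs <- sapply(reference_sets, function(refs) {
    re <- relative_expression(ct, target, refs, calibrator = calibrator,
                              base = base, collapse = collapse)
    stats::setNames(re$rel_expr, re$sample)
  })
  conc <- stats::cor(profs, method = "spearman")
  lp <- log2(profs)
  # majority consensus: element-wise median across all sets, robust to a
  # minority of discordant (unstable-reference) sets
  consensus <- apply(lp, 1, stats::median)
  score <- apply(lp, 2, stats::cor, y = consensus, method = "spearman")
  list(profiles = profs, concordance = conc, consensus_score = score,
       flagged = names(score)[score < flag_threshold])
}
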