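#' NormFinder model-based stability values
#'
#' Fits the additive two-way model \code{x_ij = alpha_i + beta_j + eps_ij} to
#' the genes-by-samples matrix of log2 relative quantities, where
#' \code{alpha_i} is a gene effect, \code{beta_j} a sample effect shared by
#' all genes, and \code{Var(eps_ij) = sigma_i^2} the gene-specific variation
#' that the stability value estimates. Because the double-centered residuals
#' of gene i are contaminated by every other gene's noise (the sample mean
#' over genes absorbs 1/k of each), the raw residual variances are
#' bias-corrected before taking the square root:
#' \deqn{\hat\sigma_i^2 = \max(0, (s_i^2 - T/(k(k-1))) \cdot k/(k-2))}
#' with \code{s_i^2} the residual variance of gene i (n - 1 denominator) and
#' \code{T} the sum of all \code{s_i^2}. Under the additive model this
#' estimator is unbiased for \code{sigma_i^2}; pre-truncation the corrected
#' variances satisfy \code{sum = T * k/(k-1)} exactly. The stability value is
#' \code{rho_i = sqrt(max(0, sigma_i^2-hat))}; smaller is more stable.
#'
#' With \code{groups}, the grouped variant additionally estimates, per gene
#' and group, the intergroup deviation
#' \code{d_ig = mean(x[i, g]) - mean(x[i, ]) - mean(x[, g]) + mean(x)},
#' shrinks it by an empirical-Bayes factor
#' \code{d~_ig = d_ig * gamma^2 / (gamma^2 + sigma^2_ig / n_g)} where
#' \code{gamma^2} is the variance of the d's in excess of their sampling
#' noise, and reports \code{rho_i = mean_g(|d~_ig| + sqrt(sigma^2_ig / n_g))}.
#'
#' @param x genes-by-samples matrix of log2 quantities (see
#'   \code{\link{to_log_quantities}}), or a \code{\link{ct_table}} /
#'   \code{quantity_matrix}, converted with base 2. At least 3 genes
#'   (the bias correction needs k >= 3) and 2 samples.
#' @param groups optional sample-to-group assignment (vector along columns,
#'   or named by sample) selecting the grouped variant; every group needs at
#'   least 2 samples.
#' @return object of class \code{normfinder}: \code{stability} (named rho,
#'   log2 units), \code{rank_of} (1 = most stable; ties broken by gene name),
#'   \code{mode}, \code{variance} (bias-corrected per-gene variance;
#'   genes-by-groups matrix in grouped mode), \code{variance_raw} (ungrouped
#'   mode: the corrected variance before truncation at zero — the unbiased
#'   estimator; truncation trades a small upward bias near zero for
#'   non-negativity) and, in grouped mode, \code{group_components} with raw
#'   and shrunken intergroup deviations.
#' @export
normfinder <- function(x, groups = NULL) {
  m <- as_log_quantities(x)
  k <- nrow(m); n <- ncol(m)
  if (k < 3) stop("NormFinder needs at least 3 genes")
  if (n < 2) stop("NormFinder needs at least 2 samples")
  if (is.null(groups)) {
    est <- nf_ungrouped(m)
    rho <- sqrt(est$sigma2)
    res <- list(stability = rho, rank_of = nf_rank(rho), mode = "ungrouped",
                variance = est$sigma2,
                variance_raw = stats::setNames(est$sigma2_raw, rownames(m)))
  } else {
    res <- nf_grouped(m, groups)
  }
  structure(res, class = "normfinder")
}

as_log_quantities <- function(x) {
  if (inherits(x, "ct_table")) return(to_log_quantities(x))
  if (inherits(x, "quantity_matrix")) return(x$log2_q)
  as.matrix(x)
}

nf_rank <- function(rho) {
  ord <- order(rho, names(rho))
  stats::setNames(match(names(rho), names(rho)[ord]), names(rho))
}

# Ungrouped machinery: double-centered residual variances with the additive
# model's bias correction. Returns both the corrected variances and the raw
# per-gene residual variances s2 (used by the grouped variant and by the
# algebraic-identity checks).
nf_ungrouped <- function(m) {
  k <- nrow(m); n <- ncol(m)
  r <- m - rowMeans(m) - rep(colMeans(m), each = k) + mean(m)
  s2 <- rowSums(r^2) / (n - 1)
  total <- sum(s2)
  corrected <- (s2 - total / (k * (k - 1))) * k / (k - 2)
  list(sigma2 = stats::setNames(pmax(corrected, 0), rownames(m)),
       sigma2_raw = corrected, s2 = s2)
}

nf_grouped <- function(m, groups) {
  k <- nrow(m)
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  groups <- as.character(groups)
  if (length(groups) != ncol(m))
    stop("groups must assign every sample (one per column)")
  glab <- unique(groups)
  if (length(glab) < 2) stop("grouped mode needs at least 2 groups")
  n_g <- table(factor(groups, glab))
  if (any(n_g < 2))
    stop("every group needs at least 2 samples; offending group(s): ",
         paste(glab[n_g < 2], collapse = ", "))

  sigma2 <- sapply(glab, function(g)
    nf_ungrouped(m[, groups == g, drop = FALSE])$sigma2)
  group_means <- sapply(glab, function(g) rowMeans(m[, groups == g, drop = FALSE]))
  overall_gene <- rowMeans(m)          # gene grand mean over all samples
  overall_group <- sapply(glab, function(g) mean(m[, groups == g]))
  d <- sweep(sweep(group_means, 1, overall_gene), 2, overall_group) + mean(m)

  sampling_var <- sweep(sigma2, 2, as.numeric(n_g), `/`)
  gamma2 <- max(0, stats::var(as.vector(d)) - mean(sampling_var))
  d_shrunk <- if (gamma2 == 0) d * 0 else d * gamma2 / (gamma2 + sampling_var)
  rho <- rowMeans(abs(d_shrunk) + sqrt(sampling_var))
  names(rho) <- rownames(m)
  list(stability = rho, rank_of = nf_rank(rho), mode = "grouped",
       variance = sigma2,
       group_components = list(d = d, d_shrunk = d_shrunk, gamma2 = gamma2,
                               n_g = as.numeric(n_g)))
}

#' @export
print.normfinder <- function(x, ...) {
  cat("NormFinder (", x$mode, ") stability values:\n", sep = "")
  ord <- order(x$rank_of)
  print(round(x$stability[ord], 4))
  invisible(x)
}
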