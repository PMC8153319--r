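#' Simulate a Ct dataset with known stability structure
#'
#' Generates threshold-cycle data under the additive model the stability
#' methods assume:
#' \deqn{Ct_{igj} = \mu_i + b_{gj} + \delta_{ig} + \epsilon_{igj}}
#' where \code{mu_i} is a gene baseline drawn uniformly in \code{mu_range},
#' \code{b_gj} a per-sample effect shared by all genes (loading/pipetting
#' variation, multiplicative on expression), \code{delta_ig ~ N(0, tau_i^2)}
#' a gene-by-tissue instability, and \code{epsilon ~ N(0, sigma_i^2)}
#' replicate noise. Normal noise on the Ct scale is multiplicative on the
#' expression scale, matching the log-scale models of geNorm, NormFinder and
#' BestKeeper. A gene's total instability is \code{sqrt(tau_i^2 + sigma_i^2)}
#' and defines the ground-truth stability order.
#'
#' The default scenario mirrors a typical tissue-panel study: 19 genes, 6
#' tissues, 3 replicates, replicate noise 0.2 cycles, gene-by-tissue
#' instability 0.2 cycles for most genes but 2.5 and 3.0 cycles for the last
#' two ("planted" unstable genes, the 2-3 cycle swings typical of the worst
#' candidates in published tissue panels), and sample-effect SD 0.5 cycles.
#'
#' @param n_genes number of genes.
#' @param n_tissues number of tissues (>= 2).
#' @param n_replicates replicates per tissue.
#' @param tau per-gene SD (cycles) of the gene-by-tissue instability; scalar
#'   or length \code{n_genes}. Default: 0.2 with the last two genes at 2.5
#'   and 2.0.
#' @param sigma per-gene replicate noise SD (cycles); scalar or vector.
#' @param sample_sd SD (cycles) of the shared per-sample effect.
#' @param mu_range window the gene baselines are drawn from (cycles).
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return list with \code{ct} (a \code{\link{ct_table}}, samples named
#'   tissue_replicate) and \code{truth} (list: mu, tau, sigma, sample_effects,
#'   delta, seed, and \code{true_order}, gene names from most to least
#'   stable).
#' @export
simulate_ct <- function(n_genes = 19, n_tissues = 6, n_replicates = 3,
                        tau = NULL, sigma = 0.2, sample_sd = 0.5,
                        mu_range = c(18, 26), seed = 1) {
  if (n_genes < 2 || n_tissues < 2 || n_replicates < 1)
    stop("invalid dimensions")
  if (is.null(tau)) {
    tau <- rep(0.2, n_genes)
    tau[n_genes] <- 3.0
    tau[n_genes - 1] <- 2.5
  }
  tau <- rep_len(tau, n_genes)
  sigma <- rep_len(sigma, n_genes)
  if (any(tau < 0) || any(sigma < 0) || sample_sd < 0)
    stop("SD parameters must be >= 0")

  genes <- sprintf("gene%02d", seq_len(n_genes))
  tissues <- sprintf("tissue%d", seq_len(n_tissues))
  with_seed(seed, {
    # scale explicit standard normals so the draw count is independent of the
    # SD parameters: runs sharing a seed differ only through the scaled terms
    mu <- stats::runif(n_genes, mu_range[1], mu_range[2])
    b <- sample_sd * stats::rnorm(n_tissues * n_replicates)
    delta <- matrix(rep(tau, n_tissues) *
                      stats::rnorm(n_genes * n_tissues),
                    n_genes, n_tissues)
    eps <- array(rep(sigma, n_tissues * n_replicates) *
                   stats::rnorm(n_genes * n_tissues * n_replicates),
                 c(n_genes, n_tissues, n_replicates))
    recs <- expand.grid(gene = seq_len(n_genes), tissue = seq_len(n_tissues),
                        replicate = seq_len(n_replicates))
    sample_idx <- (recs$tissue - 1L) * n_replicates + recs$replicate
    ct_val <- mu[recs$gene] + b[sample_idx] +
      delta[cbind(recs$gene, recs$tissue)] +
      eps[cbind(recs$gene, recs$tissue, recs$replicate)]
    tab <- ct_table(data.frame(
      gene = genes[recs$gene],
      sample = paste(tissues[recs$tissue], recs$replicate, sep = "_"),
      tissue = tissues[recs$tissue],
      replicate = recs$replicate,
      ct = ct_val, stringsAsFactors = FALSE))
    total <- sqrt(tau^2 + sigma^2)
    truth <- list(mu = stats::setNames(mu, genes),
                  tau = stats::setNames(tau, genes),
                  sigma = stats::setNames(sigma, genes),
                  sample_effects = b,
                  delta = matrix(delta, n_genes, n_tissues,
                                 dimnames = list(genes, tissues)),
                  seed = seed,
                  true_order = genes[order(total, genes)])
    list(ct = tab, truth = truth)
  })
}

#' Simulate a standard-curve dilution series
#'
#' Generates (log10 dilution, Ct) points under
#' \code{Ct = intercept - log10(dilution) / log10(1 + E)} with optional
#' normal noise, for round-trip testing of
#' \code{\link{efficiency_from_dilution}}. With zero noise the fitted
#' efficiency recovers the input exactly.
#'
#' @param efficiency_percent true amplification efficiency E x 100 (> 0).
#' @param intercept Ct at dilution 1 (log10 input 0).
#' @param noise_sd SD of additive Ct noise (cycles).
#' @param points number of ten-fold dilution points (>= 3).
#' @param seed integer seed (only relevant with noise).
#' @return data frame with columns \code{log10_dilution} (0, -1, ...) and
#'   \code{ct}.
#' @export
simulate_dilution_series <- function(efficiency_percent = 100, intercept = 30,
                                     noise_sd = 0, points = 5, seed = NULL) {
  if (efficiency_percent <= 0) stop("efficiency must be positive")
  if (points < 3) stop("need at least 3 dilution points")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  log10_dilution <- -(seq_len(points) - 1)
  slope <- -1 / log10(1 + efficiency_percent / 100)
  ct <- intercept + slope * log10_dilution
  if (noise_sd > 0)
    ct <- with_seed(seed, ct + stats::rnorm(points, 0, noise_sd))
  data.frame(log10_dilution = log10_dilution, ct = ct)
}
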