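#' Construct and validate a Ct table
#'
#' A \code{ct_table} is a long-format data frame of raw RT-qPCR threshold
#' cycle (Ct) measurements with one row per reaction: columns \code{gene},
#' \code{sample}, \code{tissue}, \code{replicate} and \code{ct}. All
#' downstream stability analyses (\code{\link{genorm}},
#' \code{\link{normfinder}}, \code{\link{bestkeeper}}) consume this shape,
#' usually after collapsing replicates to one value per gene and tissue with
#' \code{\link{ct_matrix}}.
#'
#' Validation enforces: finite Ct strictly greater than zero, unique
#' (gene, sample) pairs, and a positive integer replicate index. Matrix
#' completeness (every gene observed in every sample) is not required here;
#' it is checked where the stability methods need it.
#'
#' @param x data frame with columns \code{gene}, \code{sample},
#'   \code{tissue}, \code{replicate}, \code{ct}. \code{tissue} defaults to
#'   \code{sample} and \code{replicate} to 1 when absent.
#' @return the validated data frame with class \code{ct_table}.
#' @examples
#' ct_table(data.frame(gene = "ACT", sample = c("leaf", "root"),
#'                     ct = c(20.1, 21.4)))
#' @export
ct_table <- function(x) {
  x <- as.data.frame(x)
  if (!"tissue" %in% names(x)) x$tissue <- x$sample
  if (!"replicate" %in% names(x)) x$replicate <- 1L
  required <- c("gene", "sample", "tissue", "replicate", "ct")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("ct_table is missing column(s): ", paste(missing_cols, collapse = ", "))
  x <- x[required]
  x$gene <- as.character(x$gene)
  x$sample <- as.character(x$sample)
  x$tissue <- as.character(x$tissue)
  if (nrow(x) == 0) stop("ct_table has no records")

  bad <- which(!is.finite(x$ct) | x$ct <= 0)
  if (length(bad))
    stop("non-finite or non-positive Ct at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (gene=", paste(utils::head(x$gene[bad], 10), collapse = ","),
         ", sample=", paste(utils::head(x$sample[bad], 10), collapse = ","), ")")
  if (any(x$replicate < 1) || any(x$replicate != round(x$replicate)))
    stop("replicate must be a positive integer")
  key <- paste(x$gene, x$sample, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (gene, sample) pair(s): ",
         paste(utils::head(unique(paste0("(", x$gene[dup], ", ", x$sample[dup], ")")), 5),
               collapse = ", "))
  tpg <- unique(x[c("sample", "tissue")])
  if (anyDuplicated(tpg$sample))
    stop("a sample is annotated with more than one tissue")
  class(x) <- c("ct_table", "data.frame")
  x
}

#' Read a Ct table from a delimited text file
#'
#' @param file path to a UTF-8 delimited text file with a header row.
#' @param layout \code{"long"} (columns gene, sample, tissue, replicate, ct)
#'   or \code{"wide"} (rows are genes, columns are samples; supply per-sample
#'   tissue/replicate annotation through \code{samples}).
#' @param sep field separator; by default inferred from the file extension
#'   (\code{.csv} is comma, anything else tab).
#' @param samples for the wide layout, a data frame or file path with columns
#'   \code{sample}, \code{tissue}, \code{replicate}. Optional; when absent
#'   each sample is its own tissue with replicate 1.
#' @return a \code{\link{ct_table}}.
#' @details Non-numeric or missing Ct cells are reported with their row and
#'   column coordinates rather than silently dropped; the three stability
#'   methods all require a complete gene-by-sample matrix.
#' @export
read_ct_table <- function(file, layout = c("long", "wide"), sep = NULL,
                          samples = NULL) {
  layout <- match.arg(layout)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(file, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fill = FALSE)
  if (layout == "long") {
    required <- c("gene", "sample", "ct")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols))
      stop("long layout needs column(s): ", paste(missing_cols, collapse = ", "))
    ct_num <- suppressWarnings(as.numeric(raw$ct))
    bad <- which(is.na(ct_num))
    if (length(bad))
      stop("non-numeric Ct value(s) at row ",
           paste(bad, collapse = ", "), " column 'ct' of ", file)
    raw$ct <- ct_num
    if ("replicate" %in% names(raw))
      raw$replicate <- as.integer(raw$replicate)
    return(ct_table(raw))
  }
  # wide: first column gene names, remaining columns one sample each
  genes <- raw[[1]]
  mat <- raw[-1]
  long <- data.frame(
    gene = rep(genes, times = ncol(mat)),
    sample = rep(names(mat), each = nrow(mat)),
    ct_raw = unlist(mat, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  ct_num <- suppressWarnings(as.numeric(long$ct_raw))
  bad <- which(is.na(ct_num))
  if (length(bad))
    stop("non-numeric Ct value(s) at ",
         paste(sprintf("row '%s' column '%s'", long$gene[bad], long$sample[bad]),
               collapse = "; "), " of ", file)
  long$ct <- ct_num
  long$ct_raw <- NULL
  if (!is.null(samples)) {
    if (is.character(samples))
      samples <- utils::read.table(samples, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE)
    long <- merge(long, samples, by = "sample", sort = FALSE)
  }
  ct_table(long)
}

#' Collapse a Ct table to a gene-by-sample matrix
#'
#' Replicate collapsing follows the convention that biological and technical
#' replicates are averaged to a single Ct per gene and tissue before any
#' stability analysis; set \code{collapse = FALSE} to analyse replicate-level
#' samples directly.
#'
#' @param ct a \code{\link{ct_table}}.
#' @param collapse if \code{TRUE} (default) average all samples of a tissue
#'   so columns are tissues; if \code{FALSE} keep one column per sample.
#' @param on_missing \code{"error"} (default) to fail on an incomplete
#'   gene-by-column matrix, or \code{"drop"} to drop offending genes with a
#'   warning.
#' @return numeric matrix, genes in rows (input order of first appearance),
#'   tissues or samples in columns.
#' @export
ct_matrix <- function(ct, collapse = TRUE, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(ct, "ct_table"))
  col_id <- if (collapse) ct$tissue else ct$sample
  genes <- unique(ct$gene)
  cols <- unique(col_id)
  m <- matrix(NA_real_, length(genes), length(cols),
              dimnames = list(genes, cols))
  agg <- tapply(ct$ct, list(factor(ct$gene, genes), factor(col_id, cols)),
                mean)
  m[] <- agg
  if (anyNA(m)) {
    bad_genes <- rownames(m)[apply(m, 1, anyNA)]
    if (on_missing == "error")
      stop("incomplete Ct matrix: gene(s) missing in some column(s): ",
           paste(bad_genes, collapse = ", "))
    warning("dropping gene(s) with missing cells: ",
            paste(bad_genes, collapse = ", "))
    m <- m[setdiff(rownames(m), bad_genes), , drop = FALSE]
  }
  m
}

#' Per-tissue and per-gene Ct summary
#'
#' Collapses replicates to per-(gene, tissue) arithmetic means and sample
#' standard deviations (n - 1 denominator), then derives per-gene overall
#' statistics over the tissue means: overall mean (unweighted mean of tissue
#' means), min, max and range. The per-gene block mirrors the Average / Min /
#' Max / Range columns of a published tissue-panel Ct table.
#'
#' @param ct a \code{\link{ct_table}}.
#' @return object of class \code{tissue_summary}: list with data frames
#'   \code{cells} (gene, tissue, mean_ct, sd_ct, n) and \code{genes}
#'   (gene, overall_mean, min_ct, max_ct, range_ct).
#' @export
tissue_summary <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  if (nrow(ct) == 0) stop("empty Ct table")
  g <- factor(ct$gene, unique(ct$gene))
  t <- factor(ct$tissue, unique(ct$tissue))
  cells <- data.frame(
    gene = rep(levels(g), each = nlevels(t)),
    tissue = rep(levels(t), times = nlevels(g)),
    mean_ct = as.vector(t(tapply(ct$ct, list(g, t), mean))),
    sd_ct = as.vector(t(tapply(ct$ct, list(g, t), stats::sd))),
    n = as.vector(t(tapply(ct$ct, list(g, t), length))),
    stringsAsFactors = FALSE
  )
  cells <- cells[!is.na(cells$n), , drop = FALSE]
  rownames(cells) <- NULL
  new_tissue_summary(cells)
}

# Build the tissue_summary object from per-cell means/SDs. Used both by
# tissue_summary() and by loaders of published mean +/- SD tables.
new_tissue_summary <- function(cells) {
  per_gene <- function(x) {
    data.frame(gene = x$gene[1],
               overall_mean = mean(x$mean_ct),
               min_ct = min(x$mean_ct),
               max_ct = max(x$mean_ct),
               range_ct = max(x$mean_ct) - min(x$mean_ct),
               stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, lapply(split(cells, factor(cells$gene, unique(cells$gene))),
                                 per_gene))
  rownames(genes) <- NULL
  structure(list(cells = cells, genes = genes), class = "tissue_summary")
}

#' @export
print.tissue_summary <- function(x, ...) {
  cat("Ct tissue summary:", nrow(x$genes), "genes x",
      length(unique(x$cells$tissue)), "tissues\n")
  print(utils::head(x$genes, 10), digits = 5)
  if (nrow(x$genes) > 10) cat("...\n")
  invisible(x)
}

#' Flag genes whose Ct range across tissues exceeds a threshold
#'
#' A wide Ct range over tissue means marks a gene as too variable to serve
#' as a reference; the conventional cut-off is 4 cycles (a 16-fold swing in
#' template abundance under perfect doubling).
#'
#' @param summary a \code{\link{tissue_summary}}.
#' @param threshold cycles; genes with \code{range_ct} strictly greater are
#'   flagged. Default 4.
#' @return character vector of flagged gene names.
#' @export
flag_unstable_by_range <- function(summary, threshold = 4) {
  stopifnot(inherits(summary, "tissue_summary"), threshold >= 0)
  summary$genes$gene[summary$genes$range_ct > threshold]
}

#' Write a tissue summary as a delimited table
#'
#' One row per gene with per-tissue \code{mean +/- SD} columns followed by
#' Average, Min, Max and Range, mirroring the usual published layout.
#'
#' @param summary a \code{\link{tissue_summary}}.
#' @param file output path (tab-separated).
#' @return the written data frame, invisibly.
#' @export
write_tissue_summary <- function(summary, file) {
  stopifnot(inherits(summary, "tissue_summary"))
  cells <- summary$cells
  tissues <- unique(cells$tissue)
  wide <- summary$genes["gene"]
  for (tt in tissues) {
    sub <- cells[cells$tissue == tt, ]
    m <- sub$mean_ct[match(wide$gene, sub$gene)]
    s <- sub$sd_ct[match(wide$gene, sub$gene)]
    wide[[tt]] <- ifelse(is.na(s), sprintf("%.3f", m),
                         sprintf("%.3f ± %.3f", m, s))
  }
  wide$Average <- round(summary$genes$overall_mean, 3)
  wide$Min <- round(summary$genes$min_ct, 3)
  wide$Max <- round(summary$genes$max_ct, 3)
  wide$Range <- round(summary$genes$range_ct, 3)
  utils::write.table(wide, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(wide)
}

#' Amplification efficiency from a dilution series
#'
#' Fits ordinary least squares of Ct on log10 template input and converts the
#' slope to per-reaction amplification efficiency:
#' \code{E = (10^(-1/slope) - 1) * 100} percent. A slope of -3.32 corresponds
#' to perfect doubling (100\%).
#'
#' @param log10_dilution numeric vector of log10 input amounts (for a ten-fold
#'   series, e.g. 0, -1, -2, ...).
#' @param ct numeric vector of observed Ct values, same length.
#' @return list with \code{slope}, \code{intercept}, \code{efficiency_percent}
#'   and \code{r_squared} (squared Pearson correlation).
#' @export
efficiency_from_dilution <- function(log10_dilution, ct) {
  stopifnot(length(log10_dilution) == length(ct))
  if (length(unique(log10_dilution)) < 3)
    stop("need at least 3 distinct dilution points")
  if (stats::sd(log10_dilution) == 0) stop("zero-variance dilution series")
  fit <- stats::lm(ct ~ log10_dilution)
  slope <- unname(stats::coef(fit)[2])
  r2 <- if (stats::sd(ct) == 0) 1 else unname(stats::cor(log10_dilution, ct))^2
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       efficiency_percent = (10^(-1 / slope) - 1) * 100,
       r_squared = r2)
}
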