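test_that("long and wide readers parse, validate and report bad cells", {
  long <- data.frame(
    gene = rep(c("A", "B"), each = 3),
    sample = rep(c("s1", "s2", "s3"), 2),
    tissue = rep(c("t1", "t1", "t2"), 2),
    replicate = 1L,
    ct = c(20, 21, 22, 25, 24, 23))
  f <- tempfile(fileext = ".tsv")
  write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ct <- read_ct_table(f, layout = "long")
  expect_s3_class(ct, "ct_table")
  expect_equal(nrow(ct), 6)

  # NA cell is reported with its coordinates, not silently dropped
  long$ct[4] <- "NA"
  write.table(long, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ct_table(f, layout = "long"), "row 4")

  wide <- data.frame(gene = c("A", "B"), s1 = c(20, 25), s2 = c(21, 24))
  write.table(wide, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ctw <- read_ct_table(f, layout = "wide")
  expect_equal(nrow(ctw), 4)
  expect_equal(ctw$ct[ctw$gene == "B" & ctw$sample == "s2"], 24)

  wide$s2[1] <- "oops"
  write.table(wide, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ct_table(f, layout = "wide"), "row 'A' column 's2'")
})

test_that("ct_table rejects duplicates, non-positive Ct and bad replicates", {
  base <- data.frame(gene = "A", sample = c("s1", "s2"), ct = c(20, 21))
  expect_s3_class(ct_table(base), "ct_table")
  expect_error(ct_table(rbind(base, base[1, ])), "duplicate")
  bad <- base; bad$ct[1] <- -1
  expect_error(ct_table(bad), "non-positive")
  bad <- base; bad$replicate <- c(0L, 1L)
  expect_error(ct_table(bad), "replicate")
})

test_that("packaged tissue panel loads with the expected shape", {
  ct <- schima_ct()
  expect_equal(nrow(ct), 114)  # 19 genes x 6 tissues
  expect_setequal(unique(ct$tissue),
                  c("leaf", "bud", "fruit", "phloem", "root", "xylem"))
  expect_equal(length(unique(ct$gene)), 19)
})

test_that("tissue summary collapses replicates then summarises tissue means", {
  # 2 genes x 2 tissues x 3 replicates
  ct <- ct_table(data.frame(
    gene = rep(c("A", "B"), each = 6),
    sample = rep(paste0("s", 1:6), 2),
    tissue = rep(rep(c("t1", "t2"), each = 3), 2),
    replicate = rep(1:3, 4),
    ct = c(20, 20, 20, 22, 23, 24,  30, 31, 32, 30, 30, 30)))
  s <- tissue_summary(ct)
  a <- s$cells[s$cells$gene == "A", ]
  expect_equal(a$mean_ct, c(20, 23))
  expect_equal(a$sd_ct, c(0, 1))
  expect_equal(a$n, c(3L, 3L))
  ga <- s$genes[s$genes$gene == "A", ]
  # overall stats are over tissue means, not raw replicates
  expect_equal(ga$overall_mean, 21.5)
  expect_equal(ga$range_ct, 3)
  # single constant cell
  one <- tissue_summary(ct_table(data.frame(
    gene = "G", sample = paste0("r", 1:3), tissue = "t",
    replicate = 1:3, ct = c(20, 20, 20))))
  expect_equal(one$cells$mean_ct, 20)
  expect_equal(one$cells$sd_ct, 0)
  expect_equal(one$genes$range_ct, 0)
})

test_that("summary is invariant to record order and replicate relabeling", {
  sim <- simulate_ct(n_genes = 5, n_tissues = 3, n_replicates = 3, seed = 42)
  s1 <- tissue_summary(sim$ct)
  shuffled <- sim$ct[sample(nrow(sim$ct)), ]
  # permute replicate labels within each tissue (labels are not used in math)
  shuffled$replicate <- ave(shuffled$replicate,
                            shuffled$gene, shuffled$tissue,
                            FUN = function(r) sample(r))
  s2 <- tissue_summary(ct_table(shuffled))
  ord <- function(s) s$cells[order(s$cells$gene, s$cells$tissue), ]
  expect_equal(ord(s2), ord(s1), ignore_attr = TRUE)
  g1 <- s1$genes[order(s1$genes$gene), ]
  g2 <- s2$genes[order(s2$genes$gene), ]
  expect_equal(g2, g1, ignore_attr = TRUE)
})

test_that("published panel reproduces the printed Average and Range columns", {
  s <- schima_tissue_summary()
  g <- s$genes
  expect_equal(g$overall_mean[g$gene == "SsuMet2"], 18.032, tolerance = 1e-3)
  expect_equal(g$overall_mean[g$gene == "SsuMDH"], 25.556, tolerance = 1e-3)
  expect_equal(g$overall_mean[g$gene == "SsuACT"], 21.562, tolerance = 1e-3)
  expect_equal(g$range_ct[g$gene == "SsuCas"], 13.099, tolerance = 1e-3)
  expect_equal(g$range_ct[g$gene == "SsuUDP"], 4.731, tolerance = 1e-3)
  # structural invariants of the summary
  expect_true(all(abs(g$range_ct - (g$max_ct - g$min_ct)) < 1e-12))
  expect_true(all(g$min_ct <= g$overall_mean & g$overall_mean <= g$max_ct))
})

test_that("Ct-range screening is monotone and matches the published flags", {
  s <- schima_tissue_summary()
  expect_setequal(flag_unstable_by_range(s, 4),
                  c("SsuCas", "SsuUBC17", "SsuUBC2", "SsuUDP"))
  expect_length(flag_unstable_by_range(s, 14), 0)
  expect_equal(length(flag_unstable_by_range(s, 0)), 19)
  thresholds <- seq(0, 14, by = 0.5)
  counts <- vapply(thresholds, function(t) length(flag_unstable_by_range(s, t)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("dilution-series efficiency follows the standard-curve formula", {
  # slope of -log2(10) cycles per decade corresponds to perfect doubling
  d <- simulate_dilution_series(efficiency_percent = 100, intercept = 30,
                                points = 5)
  fit <- efficiency_from_dilution(d$log10_dilution, d$ct)
  expect_equal(fit$efficiency_percent, 100, tolerance = 1e-4)
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)

  # slope -3.5: closed form 10^(1/3.5) - 1 = 0.930572...
  fit2 <- efficiency_from_dilution(c(0, -1, -2), c(30, 33.5, 37))
  expect_equal(fit2$efficiency_percent, 93.06, tolerance = 0.05)

  # noiseless round trip at an arbitrary efficiency is exact
  d3 <- simulate_dilution_series(efficiency_percent = 93.47, intercept = 25,
                                 points = 4)
  expect_equal(efficiency_from_dilution(d3$log10_dilution, d3$ct)$efficiency_percent,
               93.47, tolerance = 1e-6)

  expect_error(efficiency_from_dilution(c(0, -1), c(30, 33)), "3 distinct")
  expect_error(efficiency_from_dilution(c(0, 0, 0), c(30, 31, 32)), "distinct")
})

test_that("noisy dilution series recovers efficiency within a few percent", {
  ests <- vapply(1:200, function(s) {
    d <- simulate_dilution_series(efficiency_percent = 95, intercept = 28,
                                  noise_sd = 0.2, points = 5, seed = s)
    efficiency_from_dilution(d$log10_dilution, d$ct)$efficiency_percent
  }, numeric(1))
  expect_lt(abs(median(ests) - 95) / 95, 0.03)
})

test_that("ct_matrix collapses to tissue means and handles missing cells", {
  sim <- simulate_ct(n_genes = 3, n_tissues = 2, n_replicates = 2, seed = 7)
  m <- ct_matrix(sim$ct)
  expect_equal(dim(m), c(3, 2))
  by_hand <- tapply(sim$ct$ct, list(sim$ct$gene, sim$ct$tissue), mean)
  expect_equal(m["gene01", "tissue1"], by_hand["gene01", "tissue1"])
  incomplete <- ct_table(
    sim$ct[!(sim$ct$gene == "gene01" & sim$ct$tissue == "tissue1"), ])
  expect_error(ct_matrix(incomplete), "incomplete")
  expect_warning(m2 <- ct_matrix(incomplete, on_missing = "drop"), "dropping")
  expect_equal(nrow(m2), 2)
})
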