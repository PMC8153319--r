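#!/usr/bin/env Rscript
# Step 2: rank the candidate reference genes with geNorm, NormFinder and
# BestKeeper, integrate the three rankings by geometric mean, and pick the
# best combination using geNorm's optimal gene number.
#
# BestKeeper is run the way the published analysis ran it: the spreadsheet
# tool caps a run at 10 genes, so the 19-gene panel was processed as two
# batches (panel order), each gene correlated against its own batch's index,
# and ranks were read off the 3-decimal display of r.

library(refstab)
suppressPackageStartupMessages(library(jsonlite))

dir.create("results", showWarnings = FALSE)

ct <- schima_ct()
res <- stability_analysis(ct, index_batch_size = 10, r_digits = 3)

# per-method outputs
write_bestkeeper(res$bestkeeper, "results/02_bestkeeper.tsv")

m_first <- res$genorm$m_trajectory[[1]]
write.table(data.frame(gene = names(m_first), M = round(m_first, 4)),
            "results/02_genorm_m_values.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(within(res$genorm$v_series, v <- round(v, 4)),
            "results/02_genorm_v_series.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
nf_tab <- data.frame(gene = names(res$normfinder$stability),
                     stability = round(res$normfinder$stability, 4),
                     rank = res$normfinder$rank_of)
write.table(nf_tab[order(nf_tab$rank), ], "results/02_normfinder.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_consensus(res$consensus, "results/02_consensus.tsv")

write_json(list(optimal_n = res$optimal_n,
                best_combination = res$best_combination,
                genorm_top = res$genorm$ranking[1:2],
                normfinder_top = names(which.min(res$normfinder$rank_of)),
                bestkeeper_top = names(which.min(res$bestkeeper$rank_of)),
                range_flagged = res$range_flagged),
           "results/02_summary.json", pretty = TRUE, auto_unbox = TRUE)

cat("geNorm: most stable pair", paste(res$genorm$ranking[1:2], collapse = " + "),
    "| least stable", rev(res$genorm$ranking)[1], "\n")
cat("geNorm pairwise variation: optimal number of reference genes =",
    res$optimal_n, "\n")
cat("NormFinder: top gene", names(which.min(res$normfinder$rank_of)),
    "(top three are near-ties:",
    paste(names(sort(res$normfinder$rank_of)[1:3]), collapse = ", "), ")\n")
cat("BestKeeper: top gene", names(which.min(res$bestkeeper$rank_of)),
    "| SD > 1 cycle:",
    paste(res$bestkeeper$table$gene[res$bestkeeper$table$sd_mad > 1],
          collapse = ", "), "\n")
cat("Consensus best combination (recomputed end to end):",
    paste(res$best_combination, collapse = " + "), "\n")

# consensus over the published per-method ranks (the published integration)
ranks <- schima_method_ranks()
cons_pub <- consensus_rank(ranks[c("gene", "genorm", "normfinder", "bestkeeper")])
cat("Consensus over the published per-method ranks:",
    paste(select_combination(cons_pub, res$optimal_n), collapse = " + "), "\n")
cat("Wrote results/02_*.tsv and results/02_summary.json\n")
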