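# Small builders shared across test files.

# Minimal long-format ct_table from a genes x samples matrix.
ct_from_matrix <- function(m, tissue = colnames(m)) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  ct_table(data.frame(
    gene = rep(rownames(m), times = ncol(m)),
    sample = rep(colnames(m), each = nrow(m)),
    tissue = rep(tissue, each = nrow(m)),
    replicate = 1L,
    ct = as.vector(m), stringsAsFactors = FALSE))
}

# Independent brute-force geNorm M: direct double loop over sd of log ratios,
# no covariance shortcut. Oracle for the engine in genorm_m().
brute_force_m <- function(q, genes = rownames(q)) {
  vapply(genes, function(j) {
    mean(vapply(setdiff(genes, j), function(k) {
      stats::sd(log2(q[j, ] / q[k, ]))
    }, numeric(1)))
  }, numeric(1))
}

# Published BestKeeper statistics (SD/CV/r columns printed at table
# precision) for the 19-gene tissue panel, keyed by gene.
printed_bestkeeper <- function() {
  read.delim(text = "gene	geo	avg	min	max	sd	cv	r
SsuACT	21.55	21.56	20.64	22.68	0.7	3.25	0.987
SsuUBCJ2	24.49	24.51	23.01	26.38	0.84	3.44	0.987
SsuCal7	20.59	20.61	19.51	21.7	0.73	3.53	0.977
SsuHis	22.05	22.07	20.62	23.43	0.8	3.63	0.93
SsuRIB	22.3	22.31	21.36	23.54	0.69	3.1	0.928
SsuUDP	24.83	24.88	23.24	27.97	1.35	5.42	0.926
SsuTUA1	23.86	23.88	22.85	25.47	0.85	3.58	0.92
SsuUBC17	21.6	21.64	20.03	24.14	1.17	5.38	0.919
SsuTUA2	21.98	21.98	21.21	22.92	0.48	2.18	0.905
SsuUBC2	21.5	21.56	19.61	24.28	1.31	6.07	0.887
SsuTUB	23.35	23.39	21.69	25.6	1.2	5.11	0.858
SsuCas	23.35	23.71	20.28	33.38	3.22	13.6	0.83
SsuMDH	25.54	25.56	24.46	26.86	0.82	3.2	0.824
SsueIF5	21.43	21.46	19.81	23.24	0.8	3.72	0.761
SsuGTP	22.86	22.87	21.98	24.3	0.52	2.28	0.742
SsuUBC1	25.31	25.32	24.18	26.41	0.68	2.68	0.741
SsuGAPDH	20.11	20.11	19.32	20.72	0.46	2.3	0.634
ColGAPDH	25.17	25.19	24.19	26.21	0.64	2.53	0.602
SsuMet2	18.01	18.03	16.75	19.27	0.78	4.35	0.513",
             stringsAsFactors = FALSE)
}
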