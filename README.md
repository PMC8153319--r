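# refstab — reference-gene stability evaluation for RT-qPCR

Relative RT-qPCR quantification stands or falls with the stability of the
reference ("housekeeping") genes used for normalization, and no gene is
stable in every species, tissue or treatment. `refstab` screens a candidate
panel from raw threshold-cycle (Ct) tables with the three standard methods
and integrates them:

* **geNorm** — stability `M_j` = mean over partners of
  `sd(log2 q_j/q_k)`; iterative exclusion of the highest-M gene yields the
  ranking (final two genes tied at rank 1), and the pairwise variation of
  consecutive normalization factors `V_n/n+1 = sd(log2 NF_n/NF_n+1)` gives
  the optimal number of reference genes (`V < 0.15`).
* **NormFinder** — additive model `x_ij = α_i + β_j + ε_ij` on log2
  quantities; gene-specific variance is estimated from double-centered
  residuals with the bias correction
  `σ̂²_i = (s²_i − T/(k(k−1)))·k/(k−2)`; stability `ρ_i = √max(0, σ̂²_i)`.
  A grouped variant (tissues as groups) with shrunken intergroup deviations
  is available for replicate-level data.
* **BestKeeper** — raw-Ct descriptive statistics (geometric/arithmetic
  mean, min, max, SD as the mean absolute deviation, CV), Pearson r of each
  gene against the per-sample geometric-mean index, and the composite
  ranking (SD ≤ 1 genes by descending r, then SD > 1 genes by ascending SD).
* **Consensus** — geometric mean of the per-method ranks with a combined
  ranking, the best combination of `optimal_n` genes, and a per-tissue
  pair rule (moderate-Ct window 20–25, lowest within-tissue SD).

Around the core: standard-curve amplification efficiency
(`E = 10^(−1/slope) − 1`), 2^−ΔΔCt relative expression with single- or
multi-gene normalization factors and cross-set concordance checks, and a
seeded synthetic Ct generator with known ground-truth stability for
validating all of the above.

The package ships the published 19-gene × 6-tissue Ct panel of *Schima
superba* (a Theaceae timber tree) as its worked fixture; the replicate-level
measurements were never deposited, so the per-tissue means — demonstrably
the input the original stability programs consumed — are the analysis-ready
data (`schima_ct()`, `schima_tissue_summary()`, `schima_method_ranks()`).

## Worked example

```r
library(refstab)

ct  <- schima_ct()                                    # 114 records, 19 x 6
res <- stability_analysis(ct, index_batch_size = 10, r_digits = 3)
print(res$genorm)
#> geNorm ranking (most stable first):
#>   SsuRIB > SsuTUA1 > SsuMDH > SsuACT > SsuCal7 > SsuTUA2 > SsuGTP > SsuHis >
#>   SsuUBCJ2 > SsueIF5 > SsuUBC1 > SsuGAPDH > ColGAPDH > SsuMet2 > SsuTUB >
#>   SsuUBC17 > SsuUBC2 > SsuUDP > SsuCas
#> optimal number of reference genes: 2

head(res$consensus[order(res$consensus$combined_rank), ], 5)
#>     gene genorm normfinder bestkeeper geo_mean_rank combined_rank
#>   SsuACT      3          2          1      1.817121             1
#>  SsuCal7      4          1          3      2.289428             2
#>   SsuRIB      1          3          5      2.466212             3
#>  SsuTUA1      1          4          6      2.884499             4
#>   SsuMDH      2          5          8      4.308869             5

select_tissue_pair(schima_tissue_summary(), "xylem")$pair
#> [1] "ColGAPDH" "SsuUBCJ2"

efficiency_from_dilution(c(0, -1, -2, -3), c(24.1, 27.4, 30.8, 34.1))$efficiency_percent
#> [1] 99.25
```

Reading the output: two reference genes suffice (`V2/3 = 0.10 < 0.15`);
geNorm's most stable pair is SsuRIB/SsuTUA1 while SsuCas and SsuUDP rank
last; BestKeeper, run the way the published analysis ran it (index batched
at the original tool's 10-gene cap, ranks read at 3-decimal display
precision of r), puts SsuACT first; and the consensus places SsuACT on top.
The recomputed NormFinder top three (SsuCal7, SsuACT, SsuRIB) are
statistical near-ties (stabilities 0, 0.06, 0.11), which is why the
end-to-end consensus pairs SsuACT with SsuCal7, whereas the consensus over
the published per-method ranks — reproduced exactly by `consensus_rank()`
on `schima_method_ranks()` — selects SsuACT + SsuRIB.

## Analysis workflow

Numbered drivers under `analysis/` rerun the full study and write tables
under `results/`:

| script | what it does |
|---|---|
| `01_ct_summary.R` | per-tissue/per-gene Ct summary, Ct-range screening (> 4 cycles) |
| `02_stability_ranking.R` | geNorm, NormFinder, BestKeeper, consensus, best combination |
| `03_tissue_pairs.R` | tissue-specific pairs via the 20–25 window / lowest-SD rule |
| `04_expression_validation.R` | 2^−ΔΔCt validation of stable vs unstable references |
| `05_simulation_study.R` | parameter-recovery rates of the three methods |

```sh
Rscript analysis/01_ct_summary.R   # and so on
```

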