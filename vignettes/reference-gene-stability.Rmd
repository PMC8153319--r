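---
title: "Evaluating RT-qPCR reference genes: geNorm, NormFinder, BestKeeper and their consensus"
author: "refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating RT-qPCR reference genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative RT-qPCR quantification divides a target gene's signal by that of
one or more reference ("housekeeping") genes, so every conclusion inherits
the assumption that the references are stably expressed across the
conditions being compared. No gene is universally stable; candidate panels
must be screened per species and per experimental design. `refstab`
implements the three screening methods that dominate this literature —
geNorm, NormFinder and BestKeeper — together with the geometric-mean rank
consensus used to integrate them, a tissue-specific gene-pair rule, the
standard-curve amplification-efficiency fit, and 2^-ddCt relative
quantification for validating the chosen references.

The package ships, as a worked fixture, the published tissue-panel Ct
summary for 19 candidate genes assayed in six tissues (leaf, bud, fruit,
phloem, root, xylem) of the subtropical timber tree *Schima superba*
(`schima_ct()`, `schima_tissue_summary()`, `schima_method_ranks()`).

## Data model and replicate collapsing

Input is a long-format table of threshold cycles: one row per (gene, sample)
with a tissue label and replicate index (`ct_table()`, `read_ct_table()`).
Lower Ct means more template; all methods need a complete gene-by-sample
matrix, so missing cells are a hard error by default (`ct_matrix()` can drop
offending genes with a warning instead).

Biological and technical replicates are averaged to one Ct per gene and
tissue before stability analysis. For the shipped panel this is provably
what the original programs consumed: the per-gene min/max/mean printed by
the BestKeeper run equal the six per-tissue means exactly. Replicate-level
analysis remains available (`ct_matrix(ct, collapse = FALSE)`), and is what
the parameter-recovery simulations use, since it carries strictly more
information.

## From Ct to relative quantities

geNorm and NormFinder operate on relative quantities
$q_{ij} = E_i^{-(Ct_{ij} - \min_j Ct_{ij})}$, with amplification base
$E_i = 2$ by default (perfect doubling) or $1 + E$ from a standard-curve
fit (`efficiency_from_dilution()`: slope of Ct on log10 input,
$E = 10^{-1/\text{slope}} - 1$). Anchoring at each gene's most expressed
sample is cosmetic: both methods are invariant to per-gene rescaling, which
the test suite asserts. BestKeeper deliberately stays on the raw Ct scale.

## geNorm

The pairwise variation between two genes is the standard deviation (n − 1
denominator throughout the package) over samples of the log2 ratio of their
quantities; a gene's stability $M_j$ is its mean pairwise variation against
the rest of the panel. The least stable gene (highest M) is excluded and M
recomputed until two genes remain; those two share rank 1 (their relative
order is undefined — a two-gene M is symmetric), and the exclusion order
fills the remaining dense ranks. Exact ties in the maximal M are broken by
excluding the lexicographically last gene name; on continuous data ties have
measure zero. Internally the engine reads all pairwise variations off one
covariance matrix ($\mathrm{var}(y_j - y_k) = C_{jj} + C_{kk} - 2C_{jk}$);
its equality with the naive double loop to 1e-12 is itself a test.

How many reference genes are enough is decided by the pairwise variation of
consecutive normalization factors: $NF_n$ is the per-sample geometric mean
of the top-n genes' quantities and $V_{n/n+1} = \mathrm{sd}(\log_2 NF_n /
NF_{n+1})$. The smallest n with $V_{n/n+1} < 0.15$ (threshold configurable)
is reported; if no V clears the threshold the full panel size is returned
with a flag. On the shipped panel $V_{2/3} = 0.10$, so two genes suffice,
and the recomputed exclusion ranking reproduces the published geNorm column
for all 19 genes.

## NormFinder

NormFinder fits the additive model $x_{ij} = \alpha_i + \beta_j +
\varepsilon_{ij}$ to the log2 quantities, where $\beta_j$ absorbs
sample-wide effects and $\mathrm{Var}(\varepsilon_{ij}) = \sigma_i^2$ is
the gene-specific instability of interest. Double-centered residuals of
gene i are contaminated by the other genes' noise (the per-sample mean over
genes carries $1/k$ of each), so the raw residual variances $s_i^2$ are
bias-corrected:

$$\hat\sigma_i^2 = \left(s_i^2 - \frac{T}{k(k-1)}\right)\frac{k}{k-2},
\qquad T = \sum_i s_i^2 .$$

These constants are derived from the model
($E[s_i^2] = \sigma_i^2 (k-2)/k + \sum_l \sigma_l^2 / k^2$), and two facts
are verified numerically rather than trusted: the pre-truncation estimates
always sum to $T\,k/(k-1)$ (algebraic identity, 1e-9), and at 10 genes by
50 samples the estimator is unbiased within Monte-Carlo error (2000
replicates keep the relative MC standard error near 2%, comfortably inside
the 5% band asserted; 500 replicates would equal the band for the smallest
variance and turn the check into a coin flip). The reported stability is
$\rho_i = \sqrt{\max(0, \hat\sigma_i^2)}$; truncation at zero buys
non-negativity at the price of a small upward bias near zero, which is why
the unbiasedness check uses the pre-truncation values (`variance_raw`).

The grouped variant (for replicate-level runs with tissues as groups)
estimates per-group variances with the same machinery, adds the intergroup
deviation $d_{ig}$ (doubly centered group means), shrinks it by an
empirical-Bayes factor $\gamma^2 / (\gamma^2 + \hat\sigma^2_{ig}/n_g)$, and
averages $|\tilde d_{ig}| + \sqrt{\hat\sigma^2_{ig}/n_g}$ over groups. The
default is ungrouped on the tissue means: six single-sample tissues cannot
form groups.

On the shipped panel the recomputed NormFinder ranks agree with the
published column for 16 of 19 genes; the three disagreements are the top
three (stability values 0, 0.06 and 0.11 — near-ties, with the smallest
estimate truncated at zero), whose published order evidently reflects the
undeposited replicate-level input. The tests therefore assert the stable
part of the claim (the identity of the top-three set and of the tail), not
the irreproducible permutation.

## BestKeeper

BestKeeper summarises each gene's raw Ct: geometric and arithmetic mean,
min, max, a dispersion "SD" and "CV". Recomputing the shipped panel shows
the published SD is the **mean absolute deviation** around the arithmetic
mean (not the n − 1 standard deviation) and CV = 100·SD/arithmetic mean;
the package follows that definition. Each gene is also correlated (Pearson,
two-sided t-based p) with the BestKeeper index, the per-sample geometric
mean of candidate Ct values. A gene with SD > 1 cycle (a two-fold swing) is
conventionally unstable whatever its r.

Two reverse-engineered properties of the published analysis are exposed as
options rather than defaults. First, the original spreadsheet caps one run
at 10 genes; the published 19-gene r values are reproduced to ±0.001 only
when the panel is split, in input order, into a batch of 10 and a batch of
9, each gene correlated against its own batch's index
(`index_batch_size = 10`). Second, the published ranking was read off the
3-decimal display of r, whose rounding ties are broken by the smaller SD
(`r_digits = 3`); at full precision two top genes swap. With both options
the composite ranking rule — SD ≤ 1 genes by descending r, then SD > 1
genes by ascending SD — reproduces the published BestKeeper column for all
19 genes. By default the index uses the whole panel at full precision.

Unlike the other two methods, BestKeeper's statistics are not invariant to
per-sample (loading) effects: a shared shift enters every gene's SD and r.
The invariance tests cover geNorm and NormFinder exactly and only the
SD-class split of BestKeeper under per-gene shifts.

## Consensus, combinations, tissue pairs

The comprehensive ranking is the geometric mean of the per-method ranks
(`consensus_rank()`), with ties broken by the best single-method rank and
then by name; input ranks may contain ties (geNorm's two rank-1 genes enter
the product as 1). The recommended combination is the top `optimal_n` genes
of the combined ranking (`select_combination()`). For single-tissue work,
`select_tissue_pair()` restricts to genes with within-tissue mean Ct in a
closed moderate-expression window (default 20–25 cycles — closed bounds
reproduce the published leaf/bud/xylem picks) and takes the two with the
smallest within-tissue SD, ties resolved by distance to the window midpoint
and then by name. On the shipped panel the rule reproduces the published
pairs for leaf, bud and xylem; for fruit, phloem and root the published
pairs are inconsistent with the stated rule (one pick lies outside the
window, another is not the lowest SD), so the rule's own output is reported
and the divergence logged by `analysis/03_tissue_pairs.R`.

## Relative expression and validation

`relative_expression()` implements 2^-ddCt: the reference level per sample
is the arithmetic mean of the reference genes' Ct (equal to a
geometric-mean normalization factor on the linear scale — asserted as an
identity in the tests), the calibrator defaults to the sample with the
highest relative target expression (the study never names its calibrator,
and this choice makes all fold changes ≤ 1 and exactly 1 at the anchor),
and a per-gene base enables efficiency-corrected runs.
`expression_profile()` compares normalizations across reference sets by
Spearman correlation of the per-sample profiles, scoring each set against
the element-wise median log2 profile of all sets — a majority consensus
robust to a minority of discordant sets (a leave-one-out consensus fails
with three sets: one bad set contaminates the two-profile median of the
others). Sets scoring below 0.8 (configurable) are flagged. With very few
samples a rank correlation is too coarse to separate sets, so the
validation simulations use 10-sample panels.

## The synthetic generator

`simulate_ct()` draws
$Ct_{igj} = \mu_i + b_{gj} + \delta_{ig} + \varepsilon_{igj}$: baselines
uniform on 18–26 cycles (the span observed in real tissue panels), shared
per-sample effects ($b$, SD 0.5 cycles — typical loading variation),
gene-by-tissue instability $\delta_{ig} \sim N(0, \tau_i^2)$ and replicate
noise $\varepsilon \sim N(0, \sigma_i^2)$. Normal noise on the Ct scale is
multiplicative on expression, matching all three methods' log-scale models.
The default scenario mirrors the study design — 19 genes, 6 tissues, 3
replicates, $\sigma = 0.2$, $\tau = 0.2$ except two planted unstable genes
with $\tau = 2.5$ and $3.0$ cycles (the 2–3 cycle swings shown by the worst
real candidates) — and the generator returns the ground-truth stability
order $\sqrt{\tau_i^2 + \sigma_i^2}$. All draws are standard normals scaled
afterwards, so runs sharing a seed differ only through the scaled terms
(this also keeps `rnorm` with zero SD from desynchronizing paired runs),
and the global RNG state is restored on exit.

What the generator does not emulate: amplification-efficiency differences
between genes, plate/position effects, melt-curve failures, non-normal
outliers, and correlated co-regulation between candidates. Passing recovery
tests therefore show the estimators work under their own model assumptions,
not that any real panel satisfies those assumptions.

## Numerical choices and limitations

* SDs use the n − 1 denominator everywhere except BestKeeper's mean
  absolute deviation, which is the tool's own definition.
* Negative NormFinder variance estimates truncate to 0; ties at zero rank
  by gene name for determinism.
* geNorm max-M ties exclude the lexicographically last name.
* Zero-variance genes get an undefined BestKeeper r and rank last in their
  SD class.
* Recovery and flagging rates quoted in the tests use 100–200 seeded runs;
  the Monte-Carlo unbiasedness check uses 2000 replicates of a 10 × 50
  panel. These sizes keep every MC standard error well below the asserted
  margins while the whole suite runs in well under a minute.
* BestKeeper's SD > 1 dichotomy estimated from only six tissue means
  misclassifies a planted 2.5-cycle gene in a few percent of panels
  (`analysis/05_simulation_study.R` quantifies this); replicate-level input
  removes the problem.
* The three methods disagree on real panels — that is why the consensus
  exists. Near-tied stability values make the exact order of the top genes
  sensitive to the input's granularity, as the NormFinder top-three
  permutation on the shipped panel illustrates.
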