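---
title: "Consensus cell-type annotation and signature scoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus cell-type annotation and signature scoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlaswalk)
```

# Overview

`atlaswalk` annotates single-cell RNA-seq data against reference atlas
profiles and compares gene-signature activity between two conditions. The
pipeline, in order:

1. **QC** — cell filters (UMI depth, mitochondrial fraction, detected-genes
   bounds) and a gene-prevalence filter.
2. **Atlas correlation** — homolog translation of the atlas into the
   sample's gene space, per-cell Pearson correlation against every atlas
   entry on a random "sketch" of cells, best correlation per type, pruning
   of rare predicted types.
3. **Consensus annotation** — a pooled pairwise marker panel, an SNN-based
   dendrogram over the sketch cells, and an iterative walk over its cuts
   that assigns each cluster the type with the maximal trimmed-mean
   correlation until the labeling is stable; labels are then projected to
   all cells.
4. **Signature scoring** — per-type Wilcoxon differential expression
   between conditions, preranked GSEA on the log2FC ranking with
   leading-edge extraction, per-cell scoring of the leading edge, and a
   two-sample Kolmogorov–Smirnov comparison of the score distributions.

Every stochastic step takes a seed derived from one root seed, so a
`pipeline_config()` fully determines all outputs.

# Quality control

`filter_cells()` keeps cells with total UMIs **strictly greater** than
`min_umis` (default 1000) and mitochondrial fraction **strictly below**
`max_mito_frac`. Mitochondrial genes are recognized by the `mt-` name
prefix (case-insensitive); if none are present the filter is skipped with
a warning rather than silently passing everything.

The `max_mito_frac` default is 0.01, i.e. 1%: "percent mitochondrial
content" cutoffs in the literature are conventionally percentages of total
UMIs, and a literal fraction of 0.0001 would discard nearly every real
cell. The parameter is fully configurable for users who want the stricter
reading. A threshold of 1 is treated as vacuous (no cell removed), so the
filter can be switched off without touching the gene names.

Detected-genes bounds (`gene_count_bounds`) remove putative doublets (high
tail) and dead cells (low tail). Because such bounds are conventionally
set by eye from the detected-genes histogram, the package deliberately has
**no default**: `propose_gene_count_bounds()` suggests quantile-based
candidates, but they must be passed explicitly to `qc_thresholds()`.

`filter_genes()` keeps genes quantified in at least 2 cells by default
(i.e. genes seen in only one cell are removed). The mitochondrial fraction
is always computed on the raw gene set, so cell and gene filters commute.

# Reference-based typing

`normalize_expression()` applies per-cell library-size scaling to a fixed
total (10,000) followed by `log1p` — the standard transform ahead of
correlation-based typing. Raw and within-cell rank transforms are
available; the rank transform makes the downstream Pearson correlation a
Spearman correlation. Atlas profiles get the matching transform inside
`correlate_cells()` so that cells and profiles are compared on the same
scale.

Correlations are computed over the intersection of the sample and atlas
gene spaces (at least 3 genes required). When a type has several atlas
entries, the best (maximum) correlation per type is kept. Zero-variance
vectors yield an undefined correlation, stored as `NA` and treated as
$-\infty$ when picking a cell's best type.

`prune_rare_types()` drops types whose share of initial best-correlation
assignments is strictly below `min_frac` (default 0.05% of the sketch
cells) and labels their cells `"ambiguous"`; shares are computed over all
sketch cells, including those about to become ambiguous. Argmax ties are
broken lexicographically by type name, deterministically.

# The consensus walk

The marker panel pools the top 30 genes (p-value ascending, ties by
absolute log2FC then name) from a Wilcoxon test for every unordered pair
of retained types. The panel feeds a cell-cell dendrogram:
20-component PCA of panel-gene expression, 20-nearest-neighbor graph
(including self), shared-nearest-neighbor Jaccard similarity, distance
$1 - \mathrm{Jaccard}$, average-linkage agglomeration. The clustering-tree
construction is the package's own reading of "an SNN graph feeding a
dendrogram"; all knobs (`n_pcs`, `snn_k`, linkage) are exposed.

`consensus_walk()` then cuts the tree at $k = 1, 2, 3, \dots$ clusters.
At each cut every cluster receives the type with the maximal 25%
trimmed-mean of its member cells' per-type correlations (25% removed from
*each* tail, the convention of `mean(trim =)`), and all member cells take
that label. A consensus score counts consecutive iterations with an
unchanged full label vector and resets to 0 on any change; the walk stops
when the score reaches `patience` (default 10). Because the singleton
partition is a fixed point, the walk always terminates within
`n_cells + patience` iterations; the tree is built once and never
recomputed during the walk. Final labels can only be retained types —
`"ambiguous"` never re-enters.

`project_labels()` carries sketch labels to the full dataset: a PCA
embedding of panel-gene space fitted on the sketch, all cells projected
into it, and each non-sketch cell taking the majority label of its 5
nearest sketch cells (ties broken by the closest tied neighbor). The
embedding, neighbor count and tie rule are package choices; they are
deliberately simple and exposed in `pipeline_config()`.

`balance_conditions()` equalizes a type's cell count across the two
conditions (per-type minimum, sampled without replacement) before
differential expression, so neither condition over-represents a type.

# Signature scoring and comparison

`wilcoxon_de()` reports, for every gene expressed in at least `min_frac`
(default 0.05) of either group, a two-sided Wilcoxon rank-sum p-value and
`log2((mean1 + 1)/(mean2 + 1))` on normalized expression. The default
`min_frac` follows the `min.pct = 0.05` convention of the popular
`FindMarkers` interface (read as the fraction 5%); the pseudocount is
configurable. Small samples (combined $n \le 25$) use the exact null
distribution — closed-form when the pooled values are tie-free,
enumeration over group assignments otherwise; larger samples use the
normal approximation with tie and continuity corrections.

`gsea_preranked()` implements the classic weighted Kolmogorov–Smirnov
running statistic over the descending-log2FC ranking: hits add
$|s|^w / \sum_{\text{hits}} |s|^w$ (default $w = 1$), misses subtract
$1/(N - N_h)$. The enrichment score is the running-sum value of maximal
absolute deviation (first such position under a $10^{-9}$ floating-point
guard, which also fixes the sign at exact $\pm$ ties). The leading edge
("core enrichment" genes) comprises the in-set genes at or before the
peak for positive ES, at or after it for negative ES. The permutation
null randomizes which ranked positions are in-set (gene-label
permutation, the preranked convention), 1,000 permutations by default,
one-sided on the observed sign with the $+1$ correction.

`score_cells()` follows three steps: each gene is divided by its maximum
over the scored population; each cell's score is the mean of the
normalized core genes; the per-cell vector is min–max rescaled to
$[0, 1]$. Max-normalization and rescaling are computed over the pooled
population (both conditions together), so the subsequent condition
comparison sees a common monotone transform — the KS statistic is
invariant under it. If all cells tie, the scores are set to 0 with a
warning (the rescale is undefined there).

`ks_compare()` computes $D = \sup_x |F_a(x) - F_b(x)|$ exactly from the
pooled order statistics and, by default, the asymptotic two-sided p-value
(Kolmogorov distribution at $\sqrt{n_1 n_2 / (n_1 + n_2)}\,D$); an exact
small-sample mode is available.

# The synthetic-data generator

`make_reference_atlas()` / `simulate_cells()` generate the structure the
pipeline assumes: a log-normal baseline expression profile shared across
types, a disjoint block of marker genes per type scaled by
$2^{\text{type\_separation}}$, per-cell library sizes from a log-normal,
counts from a single multinomial per cell in which a reserved `mt-` gene
block receives a Beta-distributed share of mass, independent per-entry
dropout, and doublets formed by averaging two distinct type profiles
(flagged in the truth table; the first type remains the "true" label,
since the pipeline removes doublets by thresholding rather than labeling
them). `simulate_condition_pair()` multiplies chosen signature genes by
$2^{\text{shift}}$ in condition B before sampling.

Default conditions, chosen once as a realistic mid-depth experiment: 4
types × 250 cells, 500 genes of which 13 are mitochondrial and 10 per
type are markers, separation 4 (markers 16× up), library sizes
LogNormal(log 2500, 0.3) (median ≈ 2,500 UMIs), 10% dropout, 2% doublets,
mitochondrial fractions Beta(2, 398) (mean 0.5%, occasional cells above
the 1% QC cutoff). What the generator does **not** emulate: batch
effects, ambient RNA, cell-cycle structure, gene–gene correlation beyond
cell type, or UMI saturation. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative model, not
performance on any particular real tissue.

# Validation and problem sizes

The test suite checks each statistic against an independent brute-force
oracle (trimmed mean vs sort-and-slice; KS $D$ vs an ECDF sup-difference
enumeration; GSEA ES vs a naive position-by-position running sum over all
proper hit subsets of lists up to length 8; exact Wilcoxon p vs full
rank-assignment enumeration), the consensus walk against a naive
reimplementation on datasets of up to 12 cells, and the full
sketch → correlate → prune → panel → tree → walk → project chain on 2,000
simulated cells (4 types, separation 4, 2% doublets), where non-doublet
label accuracy is required to reach 95% — and to collapse to chance when
separation is 0. KS calibration runs 500 null repetitions at 200 cells
per condition (type-I error required within [0.02, 0.08] at
$\alpha = 0.05$) plus a power check at a log2FC 2 shift. These sizes keep
the default suite comfortably within a desktop run while still exercising
every stage at realistic scale; `scripts/acceptance.R` re-runs the same
computations end to end and writes the resulting accuracies and rates as
JSON.

# Known limitations

- The SNN-dendrogram construction is one reasonable instantiation of a
  loosely specified family; different trees can change the walk's path
  (though rarely its fixed point on well-separated data).
- Wilcoxon DE treats cells as independent replicates, as the
  `FindMarkers`-style convention does; it is anti-conservative under
  within-sample correlation.
- The GSEA permutation null permutes gene labels, not samples, and no
  normalized enrichment score or multi-set FDR machinery is provided.
- `run_pipeline()` expects exactly two conditions sharing one gene space.
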