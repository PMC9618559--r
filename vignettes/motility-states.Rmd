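---
title: "Isolating motile tumor-cell states: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating motile tumor-cell states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`motistate` implements a signature-driven analysis of multi-tumor
single-cell RNA-seq data: cluster cells on a small motility gene
signature, score them by the geometric mean of signature expression,
contrast the extreme clusters, and order cells along a branched
low-to-high motility trajectory whose intermediate segment is mined for
metabolic "switch" genes. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic
benchmark does and does not emulate, and the design choices that were
genuinely open.

## Preprocessing

Counts are normalized to `log2(1 + 1e6 * count / total)` per cell
(`normalize_log2_cpm()`). For length-normalized input (SMART-seq TPM),
`mode = "tpm"` applies only the log transform; the mode is an explicit
flag recorded on the object, never inferred, and re-normalizing a
normalized matrix is refused. Genes detected (value > 0) in fewer than
1% of cells are removed; the boundary is strict, so a gene detected in
exactly 1% of cells survives. "Detected" is defined as a nonzero count,
the simplest defensible reading.

When malignancy annotations are absent, a simplified expression-based
copy-number profile can stand in (`cnv_score_cells()`): genes are
ordered by genomic position, centered on the mean of a reference cell
set, clipped to ±3, averaged in 100-gene moving windows within each
chromosome, and re-centered per cell on the median window (a large
amplification shifts the whole CPM composition of a cell; the median
restores the diploid baseline). A cell's scalar CNV signal is the sum
of squared window scores, and `call_malignant()` thresholds it at the
reference mean + 2 s.d. Window length, clip, and threshold are all
configurable; these constants are conventional rather than canonical,
and the module is deliberately not a full CNV inference engine — no
subclones, no allele-specific events.

## Signature clustering

Clustering operates on the cells × 10 signature submatrix. All PCA
components of that submatrix are retained (there are at most ten; no
cutoff is imposed) and concatenated with a 2-component UMAP
(`n_neighbors = 30`, `min_dist = 0.3`, fixed seed). The UMAP block is
rescaled so its total variance equals the PCA block's total variance —
without this, whichever block has larger scale dominates the Ward
distances; with it, the linear and manifold views get equal votes.
Ward agglomeration (`ward.D2`) runs on the combined coordinates; k is
chosen in 3–10 by the largest relative within-inertia gain ratio
between consecutive cuts, followed by a k-means consolidation
initialized at the cut's centroids. An explicit `k_range = k` forces k.

Two diagnostics are first-class: mean silhouette width (cluster
cohesion) and NMI between cluster labels and tumor-of-origin labels.
NMI uses arithmetic-mean normalization, `MI / mean(H_A, H_B)`, with
NMI = 0 when either partition is constant; the implementation is
checked against a direct entropy computation and against
`igraph::compare()` in the tests. Low NMI against tumors is the
quantitative form of "clustering is driven by functional state, not by
patient".

## Motility score and extreme clusters

The score is the per-cell geometric mean of signature expression with
zeros imputed to 1 *before* the log: a cell expressing no signature
gene scores exactly 1, and multiplying all (positive) expression by c
multiplies the score by c. Module scores (EMT, oRG, TEAD) use the same
formula; no rank-based or z-score variants are offered. The clusters
with the highest and lowest mean score become M-HIGH and M-LOW; a
one-way ANOVA followed by Tukey HSD (Tukey–Kramer under unequal sizes,
via `stats::TukeyHSD`) flags each extreme cluster "distinct" when all
its pairwise adjusted p-values fall below 0.01. Mean ties break by
larger cluster size, then lexicographic id, and are logged.

## Differential expression and enrichment

The shared Mann–Whitney test is exact (`stats::pwilcox`) when the
pooled sample has at most 12 tie-free observations; otherwise it uses
a tie-corrected, continuity-corrected normal approximation with an
Edgeworth kurtosis term. The U null is platykurtic at small n (excess
kurtosis `-1.2 (na² + nb² + na·nb + na + nb) / (na·nb·(n+1))`, exact
for untied ranks); the correction brings the worst-case gap to the
exact p at 6+6 from ~0.015 to ~0.002 and vanishes with n. Fold change
is defined as `2^(mean_A − mean_B)` on log2-normalized values — the
log-scale definition, chosen because every downstream threshold is
quoted on that scale. The M-HIGH list uses BH q < 0.01; enrichment
input additionally requires fold change ≥ 2 (inclusive) and q < 0.05.

Module enrichment is the upper-tail hypergeometric probability with
the universe set to the genes surviving the 1% filter; GMT collections
are tested per set with one-sided Fisher exact tests (identical to the
hypergeometric tail on the same table — the tests assert this) and BH
within the collection. Cross-dataset comparisons first restrict every
list to the genes detected in all datasets.

## Trajectory and switch genes

The signature submatrix is reduced to four spectral components:
symmetrized kNN graph (k = 30; ties at the k-th distance included, so
duplicated cells share neighborhoods), disconnected components bridged
by their closest cell pairs, normalized Laplacian eigenvectors scaled
by inverse root degree, signs fixed so the first nonzero entry is
positive — fully deterministic.

The elastic principal tree minimizes
`MSE + mu * sum(edge length²) + lambda * sum(node − neighbor-mean)²`
(defaults `mu = 0.1`, `lambda = 0.01`, 10 nodes). Growth is greedy
from a two-node segment spanning the first principal axis: every edge
bisection and every leaf attachment (at the farthest assigned cell) is
locally optimized — alternating nearest-node assignment with the
closed-form penalized least-squares node update — and the lowest-energy
candidate is kept. Energy is asserted non-increasing across accepted
steps. Branches are maximal paths between nodes of degree ≠ 2, named
S0, S1, … in discovery order. Cells project to the nearest point on
the nearest edge; junction cells are hard-assigned to that edge's
branch.

The intermediate branch set is computed from the tree geodesic between
the lowest- and highest-scoring leaf branches: branches interior to
the geodesic, plus side branches hanging off a geodesic junction whose
mean score lies strictly between the two leaf means. The side-branch
clause matters: on a three-armed "Y" — the default planted geometry —
the low-high geodesic consists of exactly two branches, and the
transition cells occupy the third arm at the junction; a
geodesic-interior-only definition would return an empty set there by
construction. A pure path with monotone scores still yields an empty
intermediate set. When the intermediate set spans several fitted
branches (the planted intermediate segment covers two adjacent state
blobs), `run_pipeline()` merges them into one meta-branch before
branch-wise DE, so the segment is tested against the low and high arms
rather than against itself. A branch marker must be higher in the
target branch with q < 0.05 in *every* pairwise comparison (BH per
comparison, matching the per-comparison q the thresholds are quoted
on); switch candidates are the intermediate markers also present in
every supplied M-HIGH list.

## The synthetic benchmark

`generate_dataset()` draws counts from a log-linear gamma-Poisson
model: gene baselines are heavy-tailed log-normal (a few
housekeeping-like genes dominate the library, as in real data — this
keeps any planted gene class a small library share, which matters
because CPM couples genes through composition), and planted effects
enter as log2 offsets. Per cell: a latent motility value (state mean ±
0.25, state means evenly spaced on 0.5–3), a discrete state (balanced
within each tumor, hence independent of tumor), a branch
(low / intermediate / high thirds of the motility range) and a branch
position. Signature genes carry nested on/off combination patterns —
genes activate progressively with the state's motility rank, two per
state step, at 6 log2 (64-fold) contrast — so every state has a
distinct combination while each gene stays monotone in motility; a
per-gene deflection (s.d. 0.7) bends intermediate-motility cells off
the low-high axis, creating the third arm of the "Y" in expression
space. Modules and the metabolic program load positively on motility
(0.3–0.7 log2 per unit); the switch gene adds a +2 log2 bump on the
intermediate branch over a mild +0.5 slope. Counts are negative
binomial (size 10, library 30,000 — deep, SMART-seq-like) followed by
independent Bernoulli dropout whose probability decays with expected
expression (`0.3 * exp(-mu/5)`): zero inflation concentrates in lowly
expressed genes, as observed in real data. A uniform dropout rate was
rejected deliberately: zeroing well-measured signature genes produces
8-log2-unit outliers that dominate Euclidean distances and make the
planted states unrecoverable by *any* distance-based clustering, which
is a property of the corruption model, not of the pipeline under test.

Default sizes (4 tumors × 250 cells × 10,000 genes) were chosen so the
suite and the acceptance script finish in minutes on one CPU; several
checks run at 600 cells, and the trajectory-topology check uses a
directly constructed geometric "Y", which isolates the tree fitter
from the embedding.

What the generator does **not** emulate: ambient RNA, doublets, UMI
duplication, batch chemistry, read-level noise, subclonal CNV
structure. Passing tests therefore demonstrate that each stage recovers
what it is designed to recover under a clean, explicit noise model —
not that the pipeline is robust to every real-data artifact.

## Numerical choices and degenerate inputs

Zero-entropy partitions give NMI 0; singleton clusters and
all-identical points give silhouette 0; a constant gene gives p = 1
and log2FC = 0; OLS on a constant response returns slope 0 and R² = 0;
`cap = 0` zeroes every CNV window; an empty intermediate set or an
empty candidate list is a logged, valid outcome. Ties in extreme-
cluster means, underpopulated branches, disconnected spectral graphs
and GMT sets outside the universe are all handled explicitly and
logged. Validation errors carry a dedicated condition class
(`motistate_validation_error`) naming the offending field or ids.

## Known limitations

The elastic tree is a deliberate simplification of full elastic-graph
learners (no pruning, no soft assignments, no branch-count model
selection); k selection inherits the known coarseness of inertia-gain
criteria on chained clusters; the CNV module is a calling heuristic,
not an inference method; and all power statements in the tests are
statements about the synthetic model above.
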