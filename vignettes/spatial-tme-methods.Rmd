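---
title: "Methods: organ-specific spatial TME analysis with spatialTME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organ-specific spatial TME analysis with spatialTME}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialTME)
```

spatialTME implements the analysis chain used in organ-specific tumor
microenvironment (TME) studies that pair imaging mass cytometry (IMC) of
tissue regions of interest (ROIs) with single-cell/nucleus RNA count
matrices: image preprocessing and segmentation, cell phenotyping, tissue
enrichment, gene-set scoring, cellular-neighborhood (CN) topology,
permutation-based interaction testing, and detection of tertiary
lymphoid structure (TLS)-like aggregates. Because suitable patient data
are rarely public, the package ships a synthetic-data generator that
plants known phenotypes, site compositions, and spatial structure, so
every statistic can be validated against ground truth. This vignette
explains the models, the parameters that matter, and the design choices
made where the methods literature leaves the details open.

## The synthetic study conditions

`generate_layout()` places cells in a half-open pixel field
\([0, W) \times [0, H)\) (origin top-left, x = column, y = row) by
rejection sampling with a minimum centroid separation (default 10 px,
twice the default nucleus radius, so each rendered nucleus is an
unambiguous connected component). Phenotypes are multinomial draws from
a per-site composition; TLS-like aggregates are disks whose members are
uniform in the disk. Aggregates use their own, smaller separation
(default 2 px) because lymphoid aggregates are an order of magnitude
denser than surrounding tissue. A single global RNG stream is seeded
per call and the seed is recorded in the ground truth; the phenotype
draw is the first RNG use, so an independent re-draw with the same seed
policy reproduces it exactly.

`render_roi()` emulates IMC acquisition: each cell contributes a nucleus
disk (radius 4 px, 20 counts/px by default) on the nucleus channel and
its phenotype's profile over a whole-cell disk (radius 7 px) on the
other channels. The observed image is the true image mixed through a
spillover matrix \(S\) (\(\mathrm{obs} = x^\top S\) per pixel,
\(S_{ii}=1\), \(S_{ij}\in[0,1)\)), plus optional Poisson shot noise and
uniformly seeded hot pixels. Channel intensity magnitudes are free
parameters (IMC provides no canonical intensity model); defaults of
10 counts/px for a phenotype's dominant marker against a 0.1 background
give contrast comparable to real ion counts.

`generate_counts()` draws gene-by-cell counts from a negative binomial
with per-phenotype means: each phenotype elevates its marker genes
(default 10 genes at mean 50 versus a baseline of median 1), and
mitochondrial genes (a configurable `MT-` prefix) hold a fixed mean so
mitochondrial fractions are realistic. Background gene means are spread
log-normally (sdlog 1) around the baseline. This matters: real count
data span several orders of magnitude of baseline expression, and any
highly-variable-gene method that standardizes against a mean–variance
trend is only meaningful when genes of similar mean exist to define
that trend. A flat baseline would make the trend degenerate at the
markers' own mean. Doublets are sums of two random parent cells,
flagged in the ground truth, and are modeled in the count matrix only
(not in images).

What the generator does **not** emulate: FFPE RNA degradation, ambient
RNA, batch effects (integration is out of scope), cell morphology beyond
disks, and spatially varying acquisition noise. Passing tests therefore
demonstrate the correctness of the statistics under clean planted
structure, not robustness to every artifact of real tissue.

## IMC preprocessing and segmentation

Processing order is fixed: spillover compensation, hot-pixel removal,
contrast enhancement, segmentation, quantification.

* **Compensation** solves, per pixel, the non-negative least-squares
  problem \(\min_{x \ge 0} \lVert x^\top S - \mathrm{obs}^\top\rVert_2\).
  The unconstrained linear solve is used where already non-negative
  (the overwhelming majority of pixels) and NNLS
  (`pracma::lsqnonneg`) elsewhere. Matrices with condition number above
  1e8 are rejected, naming the most collinear channel pair.
* **Hot pixels** are pixels exceeding the median of their 3×3
  neighborhood (center included, window clipped at borders) by more
  than a threshold (default 50 raw counts); they are replaced by that
  median. Note a consequence of the 3×3 window: any 2×2 block of hot
  pixels is majority-background in every member's window and is
  smoothed too; only larger blocks survive.
* **Contrast** clips each channel to a percentile window (defaults 0
  and 99) and rescales linearly to \([0, 1]\). All percentiles in the
  package are linear-interpolation order statistics (R's type 7),
  stated once here and used everywhere.
* **Segmentation** thresholds the nucleus channel, takes 8-connected
  components as seeds, and expands each seed by fixed-radius dilation
  (default 7 px), contested pixels going to the nearer nucleus centroid
  and ties to the lower label. The published "connectivity-aware"
  approach is not specified in detail anywhere we could follow, so this
  deterministic variant was chosen; it is exact for disk-shaped
  synthetic cells. Components found in membrane/lineage channels are
  merged into the nearest cell when their centroid lies within
  15 px of a nucleus centroid and discarded as artifacts beyond that —
  the centroid-to-centroid reading of the 15-pixel rule. The nucleus
  threshold and expansion radius are exposed in the configuration
  because the published pipeline does not state them.
* **Quantification** takes per-cell mean intensity per channel, then
  normalizes each channel to its 99th percentile across cells, clipped
  to \([0, 1]\).

## Phenotyping and the transcriptomic arm

Quality control removes genes detected in fewer than 3 cells, then
cells expressing < 500 or > 5000 genes, holding < 400 or > 25 000
UMIs, or exceeding 15% mitochondrial content — all strict
inequalities. The two filter stages iterate to a fixed point so the
operation is idempotent (a single pass is not: removing cells can push
genes back under the detection floor). Normalization scales each cell
to 10 000 counts and applies \(\ln(1+x)\).

Highly variable genes use the vst ranking: a loess fit (span 0.3,
degree 2) of log10 variance on log10 mean predicts each gene's expected
standard deviation; expression is standardized by it, clipped at
\(\sqrt{n}\), and genes are ranked by the variance of the clipped
values (top 2000 by default). The top 20 principal components of the
z-scored HVG matrix (signs fixed so each component's largest loading is
positive) feed graph clustering: exact Euclidean kNN (ties by cell
order), shared-nearest-neighbor Jaccard weights over self-inclusive
neighbor sets, pruning below 1/15, and Leiden modularity communities at
the configured resolution (1.2 for the transcriptomic arm, k = 100
Phenograph-style for the IMC arm) under a fixed seed. Leiden was chosen
because the upstream tooling's Louvain/Leiden choice is not stated and
Leiden's guarantees are strictly stronger.

Marker ranking tests each cluster against the rest with a two-sided
Wilcoxon rank-sum test after pre-filtering by detection fraction
(min.pct 0.25 in either group) and absolute log fold change (0.25). The
log fold change is \(\ln\) of de-logged mean normalized expression with
pseudocount 1 — stated explicitly because conventions differ across
tool versions. P-values are exact (full enumeration over group
assignments, tie-aware) when both groups have at most 10 cells, and
normal-approximated with tie correction otherwise; BH adjustment is
applied within each cluster's tested genes. The same rank-sum machinery
backs `compare_site_frequencies()` (Wilcoxon for two sites,
Kruskal–Wallis beyond, BH across features).

## Tissue enrichment and signature scores

`roe()` computes the ratio of observed to expected cell counts per
(cluster, site) with expected counts from the chi-squared independence
model, \(E_{cs} = n_{c\cdot} n_{\cdot s} / n\). Values above 1 flag
enrichment, below 1 depletion; entries with zero expected count are
undefined and reported as `NA`, never infinity. The statistic conserves
mass: the expected-count-weighted row average of Ro/e is exactly 1.

`ssgsea()` is the rank-based running-sum score: genes are ranked by
expression per sample (ties averaged), and the score sums, down the
ranking, the difference between the \(|r|^\alpha\)-weighted ECDF of set
members (\(\alpha\) = 0.25) and the unweighted ECDF of non-members. Raw
(un-normalized) scores are the default; dividing by the score range
across samples is available as an option because published analyses
are split on this. Being rank-based, scores are invariant under any
strictly monotone transform of expression. The tissue-resident
macrophage signature defaults to TIMD4, LYVE1, FOLR2, CCR2 plus an
MHC-II list (HLA-DRA/DRB1/DPA1/DPB1, configurable since only the family
is conventionally specified). The symbol "TIDM4" that circulates in the
literature is treated as a typo for TIMD4, but `trm_signature(timd4 =
"TIDM4")` restores the literal spelling.

## Spatial topology

Neighbor graphs are exact per-image Euclidean kNN (default k = 20, ties
by cell id) or fixed-radius; neighbors never cross image boundaries.
The CN of a cell is the phenotype composition of the window formed by
the cell **and** its 20 nearest neighbors (21 cells) — the inclusive
reading of "the center cell and its nearest 20 cells"; a flag selects
the neighbors-only window. Collagen-dominant segmented components can
participate as pseudo-cells of category "collagen I". Compositions are
clustered by k-means (k = 15 by default) with k-means++ seeding and 10
restarts under a fixed seed, keeping the lowest within-cluster sum of
squares.

The interaction test compares, per image and ordered phenotype pair
(A, B), the mean number of B neighbors per A cell against a null that
permutes phenotype labels over the image's cells while keeping the
graph fixed — the matched-randomized-tissue null that controls for both
the tissue's connectivity and its composition. P-values use the add-one
estimator \(p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(n_{\mathrm{perm}}+1)\)
so they are never zero; classification at \(\alpha\) (default 0.01,
chosen since no published level is available) is `interaction` if
\(p_{\ge}\le\alpha\), else `avoidance` if \(p_{\le}\le\alpha\), else
`none`. Exchangeability makes the test exactly calibrated by
construction; the acceptance suite verifies the empirical rate at
p ≤ 0.05 on 500 null images.

TLS-like patches are DBSCAN clusters over the cells of a target set
(default B cells and memory CD4+ T cells): a core cell has at least
`min_size` (20) target cells within `eps` (20 µm, converted through the
ROI pixel size) counting itself; cores within `eps` share a patch and
border cells attach to the first core patch reaching them in cell-id
order. These parameters are configuration, not doctrine — published
patch analyses name the idea but not the values. Patch area is the
convex hull of member centroids (shoelace formula); a concave-hull
(alpha-shape) area was considered but no computational-geometry
backend is available, and for the compact, convex-ish aggregates the
package targets the difference is small relative to the
patch-count and composition statistics that downstream comparisons
use. Patch density divides patch count by the full ROI area in mm².

## Numerical and degenerate-input conventions

Percentiles are type 7 everywhere. K-means ties and k-means++ draws,
Leiden refinement, and all noise draws run under explicit seeds;
rendered images, layouts and matrices are bit-identical under equal
seeds. Degenerate inputs follow the principle "empty is a result,
invalid is an error": a blank nucleus channel yields zero cells, an
aggregate-free layout yields zero patches, a fully filtered count
matrix yields a warning and a graceful stop, while a non-square
spillover matrix, an unknown composition category, or a signature with
no gene present in the matrix raise immediate errors.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise: Ro/e on 5×6 random
tables and a 5000-cell four-site planted layout; permutation
calibration on 500 null images of 200 cells at 500 permutations;
brute-force interaction equality on images up to 200 cells; CN recovery
on a 650-cell three-niche field and a ~1800-cell four-site fixture;
patch recovery over 20 seeded layouts; segmentation on 60-cell ROIs;
and the full transcriptomic chain on 2000 cells × 2500 genes. These
sizes were chosen so the planted effects dominate sampling noise while
a complete run stays comfortably interactive on a laptop.

## Known limitations

Batch integration and doublet classification are deliberately absent
(synthetic data are single-batch and carry ground-truth doublet flags
honored by an optional filter). Segmentation assumes compact,
roughly convex cells; it is not a replacement for learned segmentation
on real morphology. The published 9-cluster / 84 294-cell outcomes of
the motivating studies depend on patient material that is not public;
only the procedures, not those counts, are reproducible here, which is
exactly what the planted-ground-truth checks certify.
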