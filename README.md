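# spatialTME

Organ-specific spatial tumor-microenvironment (TME) analysis from
multiplexed imaging and single-cell count matrices, with a
planted-ground-truth synthetic data generator that makes every stage
testable.

Metastatic tumors remodel their immune microenvironment differently in
each host organ: lymphoid aggregates may be common in one site and
absent in another, and the spatial arrangement of phenotypes — who
neighbors whom — carries as much information as the composition itself.
Studies of this question pair imaging mass cytometry (IMC; ~40 metal
channels at ~1 µm resolution) with single-cell or single-nucleus RNA
profiling, and they rely on a now-standard analysis chain. spatialTME
implements that chain end to end for R users:

* **Image preprocessing** — per-pixel spillover compensation by
  non-negative least squares (`compensate_spillover`), hot-pixel median
  filtering (`remove_hot_pixels`), percentile contrast enhancement
  (`enhance_contrast`).
* **Segmentation and quantification** — nucleus-seeded,
  8-connectivity-aware segmentation with a 15-pixel
  centroid-distance artifact rule (`segment_cells`), and per-cell marker
  means normalized to each channel's 99th percentile (`quantify_cells`).
* **Phenotyping** — QC with the strict windows used for FFPE
  single-nucleus data (< 500 / > 5000 genes, < 400 / > 25 000 UMIs,
  > 15% mitochondrial), log-normalization, vst highly-variable genes,
  PCA, and shared-nearest-neighbor Leiden clustering that serves both
  the transcriptomic arm (resolution 1.2 on 20 PCs) and the IMC arm
  (Phenograph-style, k = 100); Wilcoxon marker ranking
  (min.pct = 0.25, logfc = 0.25) with exact small-sample p-values.
* **Enrichment** — the Ro/e statistic (observed over expected counts
  under the chi-squared independence model, `roe`), ssGSEA running-sum
  signature scores (`ssgsea`, `score_signature`, `trm_signature`), and
  site-wise frequency tests (`compare_site_frequencies`).
* **Spatial topology** — exact kNN cell graphs (`build_graph`),
  cellular-neighborhood composition over a cell and its 20 nearest
  neighbors (`cn_compose`) clustered into CN motifs by k-means with
  k = 15 (`cn_cluster`), label-permutation interaction/avoidance tests
  against a matched randomized tissue (`interaction_test`), and
  DBSCAN-based detection of TLS-like B/CD4 aggregates
  (`detect_patches`, `patch_profile`).
* **Synthetic data** — `generate_layout`, `render_roi`,
  `generate_counts` plant known phenotypes, site compositions, spillover,
  noise, aggregates, and negative-binomial counts with recorded ground
  truth; `make_fixtures` emits a complete small study.
* **Orchestration** — `pipeline_config` (every threshold with its
  conventional default), `run_imc`, `run_rna`, and a thin command-line
  wrapper in `inst/scripts/tme_pipeline.R`.

The core statistic conventions: Ro/e uses
`E(c,s) = rowtotal(c)·coltotal(s)/grandtotal` with Ro/e > 1 flagging
enrichment; the interaction statistic for an ordered pair (A, B) is the
mean number of B neighbors per A cell, with add-one permutation
p-values `p = (1 + #{perm ≥ obs}) / (n_perm + 1)`; ssGSEA sums the
difference between the |rank|^0.25-weighted ECDF of set members and the
unweighted ECDF of non-members down the expression ranking.

## Worked example

Plant a 400 × 400 µm adrenal-site layout with a TLS-like aggregate,
build the 20-nearest-neighbor graph, cluster cellular neighborhoods,
test spatial interactions, and detect patches:

```r
library(spatialTME)

lay <- generate_layout(
  300, c(B = 0.1, "CD4 T memory" = 0.1, Epithelial = 0.5, Macrophage = 0.3),
  width = 400, height = 400,
  aggregates = list(list(center = c(120, 120), radius = 30, n = 50,
                         phenotype = c(B = 0.6, "CD4 T memory" = 0.4))),
  site = "adrenal", seed = 11)

g    <- build_graph(lay$cells, "knn", k = 20)
cn   <- cn_cluster(cn_compose(lay$cells, g), k_cn = 3, seed = 11)
cn
#> <tme_cn> 350 cells in 3 cellular neighborhoods
#>   cn   n     dominant
#> 1  1 170   Epithelial
#> 2  2 111   Epithelial
#> 3  3  69 CD4 T memory

it <- interaction_test(lay$cells, g, n_perm = 1000, alpha = 0.01, seed = 11)
subset(as.data.frame(it), from == "B" & to %in% c("B", "Epithelial"))
#>  from         to observed  p_interact     p_avoid classification
#>     B          B 5.217391 0.000999001 1.000000000    interaction
#>     B Epithelial 5.565217 1.000000000 0.000999001      avoidance

ps <- detect_patches(lay$cells, c("B", "CD4 T memory"),
                     eps = 20, min_size = 20, roi_area_mm2 = c(roi = 0.16))
ps
#> <tme_patches> 1 patch(es) (eps = 20 um, min_size = 20)
#>   patch_id roi_id n_cells area_um2
#> 1        1    roi      44 1881.591
ps$density
#>  roi
#> 6.25
```

Reading the output: the aggregate surfaces as a CD4/B-dominated
cellular neighborhood (CN 3, 69 cells) inside an epithelial background;
B cells attract each other (mean 5.2 B neighbors per B cell, far above
the permutation null, p ≈ 0.001) while avoiding epithelium; and patch
detection recovers one TLS-like structure of 44 target cells
(~1882 µm², 6.25 patches/mm² for this single 0.16 mm² field) — the
planted aggregate.

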