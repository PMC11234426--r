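# Transcriptomic arm (QC -> log-normalize -> HVG -> PCA -> graph clustering ->
# marker ranking -> annotation) and Phenograph-style clustering of IMC marker
# tables.  Defaults follow common single-cell practice for FFPE material:
# cells expressing < 500 or > 5000 genes, holding < 400 or > 25000 UMIs, or
# with > 15% mitochondrial content are removed; genes seen in fewer than
# 3 cells are dropped.

#' Quality-control filter for a count matrix
#'
#' Genes detected in fewer than `min_cells_per_gene` cells are removed first;
#' cells are then removed when genes detected `< min_genes` or
#' `> max_genes`, total UMIs `< min_umi` or `> max_umi`, or mitochondrial
#' fraction `> max_mito` (all strict inequalities).  The two filters are
#' iterated to a fixed point so the operation is idempotent; QC metrics are
#' recomputed from the current matrix on each pass.
#'
#' @param x a `tme_counts`.
#' @param min_genes,max_genes genes-detected window (cells kept when
#'   `min_genes <= g <= max_genes`).
#' @param min_umi,max_umi total-UMI window.
#' @param max_mito maximum mitochondrial fraction.
#' @param min_cells_per_gene minimum cells a gene must be detected in.
#' @param drop_doublets if `TRUE` and the metadata carries a `doublet` flag,
#'   flagged barcodes are removed as well (ground-truth stand-in for a
#'   doublet classifier).
#' @return The filtered `tme_counts`; a warning (not an error) is emitted if
#'   no cell survives.
#' @export
qc_filter <- function(x, min_genes = 500, max_genes = 5000, min_umi = 400,
                      max_umi = 25000, max_mito = 0.15,
                      min_cells_per_gene = 3, drop_doublets = FALSE) {
  stopifnot(min_genes > 0, max_genes > min_genes, min_umi > 0, max_umi > min_umi)
  counts <- x$counts; meta <- x$meta
  if (drop_doublets && !is.null(meta$doublet)) {
    keep <- !meta$doublet
    counts <- counts[, keep, drop = FALSE]; meta <- meta[keep, , drop = FALSE]
  }
  mito <- startsWith(rownames(counts), x$mito_prefix)
  repeat {
    gkeep <- Matrix::rowSums(counts > 0) >= min_cells_per_gene
    counts <- counts[gkeep, , drop = FALSE]
    mito <- mito[gkeep]
    tot <- Matrix::colSums(counts)
    gdet <- Matrix::colSums(counts > 0)
    mfrac <- ifelse(tot > 0,
                    Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)
    ckeep <- !(gdet < min_genes | gdet > max_genes |
               tot < min_umi | tot > max_umi | mfrac > max_mito)
    counts <- counts[, ckeep, drop = FALSE]
    meta <- meta[ckeep, , drop = FALSE]
    if (all(gkeep) && all(ckeep)) break
    if (ncol(counts) == 0L) break
  }
  if (ncol(counts) == 0L) warnf("qc_filter removed all cells")
  meta$total_umi <- Matrix::colSums(counts)
  meta$genes_detected <- Matrix::colSums(counts > 0)
  tot <- meta$total_umi
  meta$mito_fraction <- ifelse(tot > 0,
                               Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0)
  out <- x
  out$counts <- counts; out$meta <- meta
  out
}

#' Library-size log-normalization
#'
#' Per cell, counts are scaled to a fixed library size and transformed
#' `ln(1 + x)` (the natural-log normalized expression used throughout the
#' downstream analysis).
#'
#' @param x a `tme_counts` (QC applied).
#' @param scale_factor target library size (default 10000).
#' @return A sparse genes x cells matrix of normalized expression.
#' @export
lognormalize <- function(x, scale_factor = 1e4) {
  counts <- if (inherits(x, "tme_counts")) x$counts else x
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stopf("cannot normalize: %d cell(s) with zero UMIs", sum(tot == 0))
  norm <- counts %*% Matrix::Diagonal(x = scale_factor / tot)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

# vst-style standardized variance: loess of log10(variance) on log10(mean),
# clipped standardized values, returns per-gene standardized variance.
vst_standardized_variance <- function(mat, loess_span = 0.3, clip = NULL) {
  m <- Matrix::rowMeans(mat)
  n <- ncol(mat)
  ex2 <- Matrix::rowMeans(mat^2)
  v <- (ex2 - m^2) * n / (n - 1)
  sv <- numeric(length(m))
  use <- v > 0 & m > 0
  if (sum(use) >= 4) {
    fit <- stats::loess(log10(v[use]) ~ log10(m[use]), span = loess_span,
                        degree = 2)
    esd <- sqrt(10^stats::fitted(fit))
    if (is.null(clip)) clip <- sqrt(n)
    mu <- m[use]
    dense <- as.matrix(mat[use, , drop = FALSE])
    z <- (dense - mu) / esd
    z[z > clip] <- clip
    z[z < -clip] <- -clip
    sv[use] <- apply(z, 1L, stats::var)
  } else {
    sv[use] <- v[use]
  }
  names(sv) <- rownames(mat)
  sv
}

#' Select highly variable genes (vst ranking)
#'
#' Genes are ranked by the standardized variance of the mean-variance
#' relationship: a loess regression of log10 variance on log10 mean predicts
#' each gene's expected standard deviation; values are standardized by it,
#' clipped at sqrt(n cells), and the variance of the clipped standardized
#' values is the ranking score.  Constant genes score 0.
#'
#' @param mat genes x cells matrix (counts or normalized; the ranking is
#'   applied to the matrix given).
#' @param n number of genes to return (default 2000).
#' @param loess_span span of the mean-variance loess fit.
#' @return Character vector of the top `n` gene names, by decreasing
#'   standardized variance (ties by gene order).
#' @export
select_hvg <- function(mat, n = 2000, loess_span = 0.3) {
  if (inherits(mat, "tme_counts")) mat <- mat$counts
  if (n > nrow(mat)) stopf("n = %d exceeds gene count %d", n, nrow(mat))
  sv <- vst_standardized_variance(mat, loess_span)
  rownames(mat)[order(-sv)][seq_len(n)]
}

#' PCA embedding of the scaled HVG matrix
#'
#' Genes are z-scored across cells (optionally clipped), and cells are
#' embedded on the top principal components.  The sign of each PC is fixed
#' so its largest-magnitude gene loading is positive.
#'
#' @param norm genes x cells normalized matrix.
#' @param hvg gene subset to use (default: all rows).
#' @param n_pcs number of components (default 20).
#' @param scale_max clip for scaled expression (default 10).
#' @return cells x n_pcs matrix; attributes `sdev` (component standard
#'   deviations) and `loadings`.
#' @export
embed_pca <- function(norm, hvg = rownames(norm), n_pcs = 20, scale_max = 10) {
  x <- as.matrix(norm[hvg, , drop = FALSE])
  if (n_pcs > min(dim(x))) stopf("n_pcs exceeds min(genes, cells)")
  sds <- apply(x, 1L, stats::sd)
  sds[sds == 0] <- 1
  z <- (x - rowMeans(x)) / sds
  z[z > scale_max] <- scale_max
  p <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(p$x))
  if (k < n_pcs) warnf("rank %d < n_pcs = %d; truncating", k, n_pcs)
  emb <- p$x[, seq_len(k), drop = FALSE]
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) { emb[, j] <- -emb[, j]; rot[, j] <- -rot[, j] }
  }
  attr(emb, "sdev") <- p$sdev[seq_len(k)]
  attr(emb, "loadings") <- rot
  emb
}

knn_indices <- function(x, k) {
  d2 <- cross_dist2(x, x)
  n <- nrow(x)
  t(vapply(seq_len(n), function(i) {
    o <- order(d2[i, -i])  # ties broken by index order
    cand <- seq_len(n)[-i][o]
    cand[seq_len(k)]
  }, integer(k)))
}

#' Graph-based clustering (shared-nearest-neighbor modularity communities)
#'
#' Builds the exact Euclidean k-nearest-neighbor graph (ties by point
#' index), re-weights edges by the Jaccard overlap of neighbor sets
#' (Phenograph / Seurat SNN construction; each cell's set includes itself),
#' prunes weak edges, and partitions by Leiden modularity optimization at
#' the given resolution under a fixed seed.  The same operation serves the
#' transcriptomic arm (e.g. `k = 20`, `resolution = 1.2` on 20 PCs) and the
#' IMC marker arm (`k = 100`, Phenograph-style).
#'
#' @param x cells x features matrix (PC embedding or marker table).
#' @param k_neighbors neighbors per cell; must be `< nrow(x)`.
#' @param resolution modularity resolution (default 1).
#' @param prune Jaccard threshold below which SNN edges are dropped
#'   (default 1/15).
#' @param seed RNG seed for the community search.
#' @param n_iterations Leiden iterations.
#' @return A list of class `tme_clusters`: `cluster` (integer per cell,
#'   contiguous ids ordered by decreasing size), `k`, `resolution`,
#'   `means` (cluster x feature means).
#' @export
cluster_graph <- function(x, k_neighbors, resolution = 1, prune = 1 / 15,
                          seed = 1L, n_iterations = 10L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k_neighbors >= n) stopf("k_neighbors (%d) must be < number of cells (%d)",
                              k_neighbors, n)
  nn <- knn_indices(x, k_neighbors)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  # candidate edges: i -- j for j in knn(i)
  ii <- rep(seq_len(n), each = k_neighbors)
  jj <- as.vector(t(nn))
  pairs <- unique(cbind(pmin(ii, jj), pmax(ii, jj)))
  w <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- sets[[pairs[r, 1]]]; b <- sets[[pairs[r, 2]]]
    inter <- length(intersect(a, b))
    inter / (length(a) + length(b) - inter)
  }, numeric(1))
  ok <- w >= prune
  g <- igraph::graph_from_edgelist(pairs[ok, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w[ok]
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  memb <- relabel_by_size(igraph::membership(cl))
  means <- do.call(rbind, lapply(sort(unique(memb)), function(k)
    colMeans(x[memb == k, , drop = FALSE])))
  structure(list(cluster = memb, k = k_neighbors, resolution = resolution,
                 means = means, seed = seed),
            class = "tme_clusters")
}

#' @export
print.tme_clusters <- function(x, ...) {
  cat(sprintf("<tme_clusters> %d cells in %d clusters (k = %d, resolution = %g)\n",
              length(x$cluster), max(x$cluster), x$k, x$resolution))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Rank cluster marker genes (Wilcoxon rank-sum)
#'
#' For each cluster versus all other cells: genes are pre-filtered by
#' detection fraction >= `min_pct` in either group and absolute log fold
#' change >= `logfc_threshold`; surviving genes get a two-sided Wilcoxon
#' rank-sum p-value (exact enumeration when both groups have <= 10 cells)
#' and Benjamini-Hochberg adjustment across the genes tested within the
#' cluster.  Log fold change is
#' `ln((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1))`, i.e. computed
#' on de-logged normalized expression with pseudocount 1.
#'
#' @param norm genes x cells normalized matrix.
#' @param clusters integer cluster per cell (or a `tme_clusters`).
#' @param min_pct minimum detection fraction (default 0.25).
#' @param logfc_threshold minimum |log FC| (default 0.25).
#' @return data.frame: `cluster`, `gene`, `log_fc`, `pct_in`, `pct_out`,
#'   `p_value`, `p_adj`, sorted by cluster then p.
#' @export
rank_markers <- function(norm, clusters, min_pct = 0.25, logfc_threshold = 0.25) {
  if (inherits(clusters, "tme_clusters")) clusters <- clusters$cluster
  ids <- sort(unique(clusters))
  if (length(ids) < 2L) stopf("need >= 2 clusters")
  res <- list()
  dense <- as.matrix(norm)
  for (cl in ids) {
    in_idx <- which(clusters == cl)
    if (length(in_idx) < 2L) {
      warnf("cluster %s has < 2 cells; skipped", cl)
      next
    }
    out_idx <- which(clusters != cl)
    xin <- dense[, in_idx, drop = FALSE]
    xout <- dense[, out_idx, drop = FALSE]
    pct_in <- rowMeans(xin > 0); pct_out <- rowMeans(xout > 0)
    lfc <- log((rowMeans(expm1(xin)) + 1) / (rowMeans(expm1(xout)) + 1))
    test <- which(pmax(pct_in, pct_out) >= min_pct & abs(lfc) >= logfc_threshold)
    if (!length(test)) next
    p <- vapply(test, function(g)
      rank_sum_test(xin[g, ], xout[g, ])$p.value, numeric(1))
    res[[length(res) + 1L]] <- data.frame(
      cluster = cl, gene = rownames(dense)[test], log_fc = lfc[test],
      pct_in = pct_in[test], pct_out = pct_out[test], p_value = p,
      p_adj = stats::p.adjust(p, "BH"), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(cluster = integer(0), gene = character(0),
                                      log_fc = numeric(0), pct_in = numeric(0),
                                      pct_out = numeric(0), p_value = numeric(0),
                                      p_adj = numeric(0)))
  out[order(out$cluster, out$p_value), ]
}

#' Annotate clusters with canonical marker sets
#'
#' Each cluster receives the label whose marker genes have the highest mean
#' scaled (z-scored across cells) expression within the cluster; ties are
#' broken alphabetically with a warning.  Markers absent from the matrix are
#' skipped with a warning.
#'
#' @param norm genes x cells normalized matrix.
#' @param clusters integer cluster per cell (or `tme_clusters`).
#' @param marker_map named list: label -> character vector of marker genes.
#' @return data.frame `cluster`, `label`, `score`.
#' @export
annotate_clusters <- function(norm, clusters, marker_map) {
  if (inherits(clusters, "tme_clusters")) clusters <- clusters$cluster
  if (!length(marker_map)) stopf("marker_map must be non-empty")
  dense <- as.matrix(norm)
  sds <- apply(dense, 1L, stats::sd)
  sds[sds == 0] <- 1
  z <- (dense - rowMeans(dense)) / sds
  ids <- sort(unique(clusters))
  scores <- matrix(NA_real_, length(ids), length(marker_map),
                   dimnames = list(ids, names(marker_map)))
  for (lab in names(marker_map)) {
    genes <- intersect(marker_map[[lab]], rownames(dense))
    if (!length(genes)) {
      warnf("no marker of '%s' present in the matrix; label skipped", lab)
      next
    }
    if (length(genes) < length(marker_map[[lab]]))
      warnf("label '%s': markers absent and skipped: %s", lab,
            paste(setdiff(marker_map[[lab]], genes), collapse = ", "))
    for (i in seq_along(ids))
      scores[i, lab] <- mean(z[genes, clusters == ids[i], drop = FALSE])
  }
  if (all(is.na(scores))) stopf("no label had any marker present")
  lab_order <- order(colnames(scores))  # alphabetical tie-break
  best <- apply(scores[, lab_order, drop = FALSE], 1L, function(s) {
    top <- which(s == max(s, na.rm = TRUE))
    if (length(top) > 1L) warnf("annotation tie broken alphabetically")
    top[1]
  })
  data.frame(cluster = ids,
             label = colnames(scores)[lab_order][best],
             score = apply(scores, 1L, max, na.rm = TRUE),
             stringsAsFactors = FALSE)
}
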