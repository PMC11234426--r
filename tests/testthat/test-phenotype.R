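# Build a tme_counts from a dense matrix without QC-relevant randomness.
counts_from_dense <- function(m, mito_prefix = "MT-", site = "s1") {
  rownames(m) <- rownames(m) %||% sprintf("G%03d", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% sprintf("c%03d", seq_len(ncol(m)))
  make_counts(m, site = site, mito_prefix = mito_prefix)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("qc_filter matches the brute-force oracle, boundaries included", {
  # randomized toys with cells planted exactly at the quoted boundaries
  for (seed in 1:3) {
    set.seed(seed)
    n_genes <- 600; n_cells <- 40
    m <- matrix(rpois(n_genes * n_cells, 1.2), n_genes, n_cells)
    mito_rows <- 1:5
    rownames(m) <- c(paste0("MT-", 1:5), sprintf("G%03d", 1:(n_genes - 5)))
    # plant boundary cells: exactly 500 genes detected, and mito exactly 15%
    m[, 1] <- 0; m[2:501, 1] <- 1                      # 500 genes, 500 UMIs
    m[, 2] <- 0; m[2:500, 2] <- 1; m[501, 2] <- 1      # 500 genes
    m[, 3] <- 0; m[6:504, 3] <- 1; m[1, 3] <- 88       # mito 88/587 ~ 0.1499
    m[, 4] <- 0; m[6:504, 4] <- 1; m[1, 4] <- 89       # mito just above 0.15
    x <- counts_from_dense(m)
    filt <- qc_filter(x, min_genes = 100, max_genes = 5000, min_umi = 400,
                      max_umi = 25000, max_mito = 0.15, min_cells_per_gene = 3)
    oracle <- oracle_qc(m, startsWith(rownames(m), "MT-"),
                        min_genes = 100, max_genes = 5000, min_umi = 400,
                        max_umi = 25000, max_mito = 0.15, min_cells_per_gene = 3)
    expect_identical(dim(filt$counts), dim(oracle))
    expect_equal(as.matrix(filt$counts), oracle, ignore_attr = TRUE)
  }
})

test_that("qc_filter applies the strict-inequality windows and gene floor", {
  # 6 cells bracketing the gene windows; generous gene pool so the
  # min-cells-per-gene filter does not interact
  n_genes <- 5205
  m <- matrix(0, n_genes, 6)
  rownames(m) <- c(sprintf("G%04d", 1:5200), paste0("MT-", 1:5))
  gd <- c(499, 500, 5000, 5001, 2000, 2000)
  for (j in 1:6) m[seq_len(gd[j]), j] <- 1
  # pad each cell to 10000 UMIs via its first gene (shared by all cells)
  for (j in 1:6) m[1, j] <- m[1, j] + (10000 - sum(m[, j]))
  # mito loads on the last two cells: 0.10 and 0.16 of total
  m[5201, 5] <- 1000; m[1, 5] <- m[1, 5] - 1000
  m[5201, 6] <- 1600; m[1, 6] <- m[1, 6] - 1600
  x <- counts_from_dense(m)
  filt <- qc_filter(x)
  oracle <- oracle_qc(m, startsWith(rownames(m), "MT-"))
  expect_equal(as.matrix(filt$counts), oracle, ignore_attr = TRUE)
  # survivors: the oracle keeps cells respecting < 500 / > 5000 / > 0.15
  expect_identical(ncol(filt$counts), ncol(oracle))

  # a gene present in exactly 2 cells is removed; in exactly 3, kept
  m2 <- matrix(1, 600, 5)
  rownames(m2) <- sprintf("G%03d", 1:600)
  m2[1, 3:5] <- 0   # gene 1 in 2 cells
  m2[2, 4:5] <- 0   # gene 2 in 3 cells
  x2 <- counts_from_dense(m2)
  f2 <- qc_filter(x2, min_genes = 100, max_genes = 5000, min_umi = 100,
                  max_umi = 25000)
  expect_false("G001" %in% rownames(f2$counts))
  expect_true("G002" %in% rownames(f2$counts))

  # idempotence
  f3 <- qc_filter(f2, min_genes = 100, max_genes = 5000, min_umi = 100,
                  max_umi = 25000)
  expect_identical(as.matrix(f3$counts), as.matrix(f2$counts))

  # already-clean matrix unchanged
  expect_identical(dim(qc_filter(x2, min_genes = 100, max_genes = 5000,
                                 min_umi = 100, max_umi = 25000)$counts),
                   dim(f2$counts))
})

test_that("qc_filter empties gracefully and honors doublet flags", {
  m <- matrix(5, 50, 4)
  x <- counts_from_dense(m)
  expect_warning(empty <- qc_filter(x, min_genes = 100, max_genes = 200,
                                    min_umi = 1, max_umi = 10),
                 "removed all cells")
  expect_identical(ncol(empty$counts), 0L)

  xd <- generate_counts(100, c(A = 1), n_genes = 1500, doublet_rate = 0.2,
                        seed = 3)
  fd <- qc_filter(xd, min_genes = 10, max_genes = 1e6, min_umi = 10,
                  max_umi = 1e9, drop_doublets = TRUE)
  expect_false(any(fd$meta$doublet))
})

test_that("lognormalize: library scaling, zeros, scale invariance", {
  m <- matrix(c(1, 1, 0, 3), 2, 2)
  rownames(m) <- c("G1", "G2")
  x <- counts_from_dense(m)
  norm <- lognormalize(x, scale_factor = 1e4)
  expect_equal(as.numeric(norm[, 1]), c(log(5001), log(5001)))
  expect_equal(as.numeric(norm[1, 2]), 0)  # zero stays zero

  # doubling a cell's counts leaves its normalized vector unchanged
  m2 <- cbind(a = c(3, 7, 0), b = 2 * c(3, 7, 0))
  x2 <- counts_from_dense(m2)
  n2 <- lognormalize(x2)
  expect_equal(as.numeric(n2[, 1]), as.numeric(n2[, 2]))

  x3 <- counts_from_dense(cbind(c(1, 1), c(0, 0)))
  expect_error(lognormalize(x3), "zero UMIs")
})

test_that("select_hvg ranks by standardized variance of the vst fit", {
  set.seed(11)
  n <- 200
  m <- matrix(rpois(50 * n, 5), 50, n)
  rownames(m) <- sprintf("G%02d", 1:50)
  # one gene with inflated variance at matched mean: overdispersed mixture
  g_hot <- 25
  m[g_hot, ] <- ifelse(runif(n) < 0.5, 0, 10)   # mean 5, far higher variance
  expect_identical(select_hvg(m, n = 50), rownames(m)[order(-vst_rank_oracle(m))][1:50])
  expect_identical(sort(select_hvg(m, n = 50)), sort(rownames(m)))  # n = all
  top <- select_hvg(m, n = 5)
  expect_true(rownames(m)[g_hot] %in% top)
  expect_identical(select_hvg(m, n = 1), rownames(m)[g_hot])

  # constant gene never beats any varying gene
  m[10, ] <- 7
  sel <- select_hvg(m, n = 49)
  expect_false("G10" %in% sel)

  expect_error(select_hvg(m, n = 51), "exceeds")
})

test_that("embed_pca: closed-form 2-gene toy, rotation invariance, sign fix", {
  # perfectly anticorrelated genes: PC1 captures ~100% of variance
  set.seed(12)
  g <- rnorm(100)
  norm <- rbind(G1 = g, G2 = -g + rnorm(100, sd = 1e-3))
  emb <- embed_pca(norm, n_pcs = 2)
  sdev <- attr(emb, "sdev")
  expect_gte(sdev[1]^2 / sum(sdev^2), 0.99)

  # orthogonal rotation of the feature space preserves the spectrum
  set.seed(13)
  x <- matrix(rnorm(20 * 50), 20, 50)
  rownames(x) <- sprintf("G%02d", 1:20)
  q <- qr.Q(qr(matrix(rnorm(400), 20)))
  xr <- q %*% x
  rownames(xr) <- rownames(x)
  # rotation changes per-gene variances, so compare unscaled PCA spectra
  e1 <- prcomp(t(x))$sdev
  e2 <- prcomp(t(xr))$sdev
  expect_equal(e1, e2, tolerance = 1e-8)

  # n_pcs = 1 on one gene: embedding is the (scaled, centered) gene
  one <- matrix(seq(0, 1, length.out = 30), 1, dimnames = list("G1", NULL))
  e <- embed_pca(one, n_pcs = 1, scale_max = 100)
  v <- (one[1, ] - mean(one[1, ])) / sd(one[1, ])
  expect_equal(abs(as.numeric(e)), abs(v - mean(v)), tolerance = 1e-8)
  # sign convention: the largest-magnitude loading is positive
  expect_gte(max(attr(e, "loadings")), 0)

  expect_error(embed_pca(norm, n_pcs = 50), "n_pcs")
})

test_that("cluster_graph separates planted blobs and respects limits", {
  # two Gaussian blobs in the dimensionality of a PC embedding, centers
  # 10 sigma apart along one axis
  set.seed(14)
  blob <- matrix(rnorm(400 * 20), 400, 20)
  blob[201:400, 1] <- blob[201:400, 1] + 10
  truth <- rep(1:2, each = 200)
  cl <- cluster_graph(blob, k_neighbors = 15, resolution = 1, seed = 5)
  expect_equal(max(cl$cluster), 2)
  expect_equal(adjusted_rand_index(cl$cluster, truth), 1)
  expect_equal(ari_oracle(cl$cluster, truth), 1)  # cross-check vs mclust

  # determinism under the seed
  cl2 <- cluster_graph(blob, k_neighbors = 15, resolution = 1, seed = 5)
  expect_identical(cl$cluster, cl2$cluster)

  # resolution -> 0 on a connected graph: a single community
  cl0 <- cluster_graph(blob[1:200, ], k_neighbors = 15, resolution = 1e-4,
                       seed = 5)
  expect_equal(max(cl0$cluster), 1)

  # duplicating every point keeps duplicates together
  dup <- rbind(blob, blob)
  cld <- cluster_graph(dup, k_neighbors = 15, resolution = 1, seed = 5)
  expect_identical(cld$cluster[1:400], cld$cluster[401:800])

  expect_error(cluster_graph(blob, k_neighbors = 400), "must be <")
})

test_that("rank_markers: exact Wilcoxon oracle, symmetric under label swap", {
  # 10 cells, one separating gene, one flat gene
  norm <- rbind(
    SEP  = c(5, 6, 7, 5.5, 6.5, 0.1, 0.2, 0.1, 0.3, 0.2),
    FLAT = rep(2, 10),
    MID  = c(1, 2, 1, 2, 1, 1.1, 2.1, 1.2, 2.2, 1.1))
  cl <- rep(1:2, each = 5)
  res <- rank_markers(norm, cl, min_pct = 0.25, logfc_threshold = 0.25)
  sep1 <- res[res$cluster == 1 & res$gene == "SEP", ]
  expect_equal(sep1$p_value,
               oracle_ranksum_p(norm["SEP", 1:5], norm["SEP", 6:10]))
  # exact enumeration for 5v5 distinct values: minimal two-sided p = 2/252
  expect_equal(sep1$p_value, 2 / choose(10, 5))
  expect_false("FLAT" %in% res$gene)   # identical groups never pass log-FC

  # swapping group labels flips the log-FC sign and preserves p
  res_sw <- rank_markers(norm, 3 - cl, min_pct = 0.25, logfc_threshold = 0.25)
  sep2 <- res_sw[res_sw$cluster == 2 & res_sw$gene == "SEP", ]
  expect_equal(sep2$log_fc, -res_sw[res_sw$cluster == 1 & res_sw$gene == "SEP", "log_fc"])
  expect_equal(sep1$p_value, sep2$p_value)

  # log-FC convention: ln of de-logged means with pseudocount 1
  lfc_oracle <- log((mean(expm1(norm["SEP", 1:5])) + 1) /
                    (mean(expm1(norm["SEP", 6:10])) + 1))
  expect_equal(sep1$log_fc, lfc_oracle)

  expect_error(rank_markers(norm, rep(1, 10)), "clusters")
  expect_warning(rank_markers(norm, c(1, rep(2, 9))), "skipped")
})

test_that("annotate_clusters picks the top marker set, with tie and miss warnings", {
  set.seed(15)
  norm <- matrix(rnorm(6 * 60, 1), 6, 60)
  rownames(norm) <- c("EBF1", "BANK1", "CD3E", "SKAP1", "MUC1", "SFTPB")
  cl <- rep(1:3, each = 20)
  norm[c("EBF1", "BANK1"), cl == 1] <- norm[c("EBF1", "BANK1"), cl == 1] + 4
  norm[c("CD3E", "SKAP1"), cl == 2] <- norm[c("CD3E", "SKAP1"), cl == 2] + 4
  norm[c("MUC1", "SFTPB"), cl == 3] <- norm[c("MUC1", "SFTPB"), cl == 3] + 4
  map <- list("B cells" = c("EBF1", "BANK1"),
              "T cells" = c("CD3E", "SKAP1"),
              "Epithelial" = c("MUC1", "SFTPB"))
  ann <- annotate_clusters(norm, cl, map)
  expect_identical(ann$label, c("B cells", "T cells", "Epithelial"))

  # single cluster: a single row with some argmax label (z-scoring within
  # one cluster is degenerate, so only the structure is asserted)
  ann1 <- annotate_clusters(norm, rep(1, 60), map)
  expect_equal(nrow(ann1), 1)
  expect_true(ann1$label %in% names(map))

  expect_error(annotate_clusters(norm, cl, list()), "non-empty")
  expect_warning(annotate_clusters(norm, cl, c(map, list(Mast = c("KIT")))),
                 "skipped")
})
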