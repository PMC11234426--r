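# Independent oracles and tiny constructors shared across test files.
# Each oracle is written as plain loops, deliberately apart from the
# package's vectorized implementations.

# Build a tme_roi directly from a pixel array (H x W x C) and a panel,
# bypassing the renderer.
make_test_roi <- function(pixels, panel, roi_id = "t", site = "s",
                          pixel_size = 1) {
  dimnames(pixels) <- list(NULL, NULL, panel$marker)
  structure(list(pixels = pixels, panel = panel, roi_id = roi_id,
                 site = site, pixel_size = pixel_size),
            class = "tme_roi")
}

test_panel3 <- function() {
  spatialTME::imc_panel(c("DNA1", "mA", "mB"),
                        c("nucleus", "lineage", "lineage"))
}

# Brute-force 3x3 median filter (center included, window clipped at borders).
oracle_median3x3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- m
  for (i in seq_len(H)) for (j in seq_len(W)) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- median(vals)
  }
  out
}

# Brute-force QC filter on a dense matrix with the quoted strict
# inequalities, iterated to a fixed point (genes-then-cells per pass).
oracle_qc <- function(mat, mito, min_genes = 500, max_genes = 5000,
                      min_umi = 400, max_umi = 25000, max_mito = 0.15,
                      min_cells_per_gene = 3) {
  repeat {
    det_cells <- sapply(seq_len(nrow(mat)), function(g) sum(mat[g, ] > 0))
    gk <- det_cells >= min_cells_per_gene
    mat <- mat[gk, , drop = FALSE]; mito <- mito[gk]
    keep <- logical(ncol(mat))
    for (j in seq_len(ncol(mat))) {
      g <- sum(mat[, j] > 0); u <- sum(mat[, j])
      mf <- if (u > 0) sum(mat[mito, j]) / u else 0
      keep[j] <- !(g < min_genes || g > max_genes || u < min_umi ||
                   u > max_umi || mf > max_mito)
    }
    mat <- mat[, keep, drop = FALSE]
    if (all(gk) && all(keep)) break
    if (ncol(mat) == 0) break
  }
  mat
}

# ssGSEA running sum spelled out position by position.
oracle_ssgsea <- function(v, members, alpha) {
  rv <- rank(v, ties.method = "average")
  ord <- order(-rv, seq_along(v))
  N <- length(v)
  denom_in <- sum(abs(rv[members])^alpha)
  n_out <- N - length(members)
  score <- 0; acc_in <- 0; acc_out <- 0
  for (pos in seq_len(N)) {
    g <- ord[pos]
    if (g %in% members) acc_in <- acc_in + abs(rv[g])^alpha
    else acc_out <- acc_out + 1
    score <- score + (acc_in / denom_in - acc_out / n_out)
  }
  unname(score)
}

# Exact two-sided rank-sum p by explicit enumeration of group assignments.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  obs <- sum(r[1:n1])
  e <- n1 * (n1 + n2 + 1) / 2
  cmb <- combn(n1 + n2, n1)
  hits <- 0
  for (c in seq_len(ncol(cmb))) {
    s <- sum(r[cmb[, c]])
    if (abs(s - e) >= abs(obs - e) - 1e-12) hits <- hits + 1
  }
  hits / ncol(cmb)
}

# Expected counts and Ro/e by explicit loops.
oracle_roe <- function(obs) {
  out <- obs * NA_real_
  for (i in seq_len(nrow(obs))) for (j in seq_len(ncol(obs))) {
    e <- sum(obs[i, ]) * sum(obs[, j]) / sum(obs)
    out[i, j] <- if (e == 0) NA_real_ else obs[i, j] / e
  }
  out
}

# independent re-ranking oracle for the vst highly-variable-gene score
vst_rank_oracle <- function(m) {
  mu <- rowMeans(m); v <- apply(m, 1, var)
  use <- v > 0 & mu > 0
  fit <- loess(log10(v[use]) ~ log10(mu[use]), span = 0.3, degree = 2)
  esd <- sqrt(10^fitted(fit))
  clip <- sqrt(ncol(m))
  sv <- numeric(nrow(m))
  z <- (m[use, ] - mu[use]) / esd
  z[z > clip] <- clip; z[z < -clip] <- -clip
  sv[use] <- apply(z, 1, var)
  sv
}

ari_oracle <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    mclust::adjustedRandIndex(a, b)
  else spatialTME::adjusted_rand_index(a, b)
}
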