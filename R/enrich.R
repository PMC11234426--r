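# Tissue enrichment (Ro/e), ssGSEA signature scoring, and site-wise
# frequency comparisons.

#' Ratio of observed to expected cell numbers (Ro/e)
#'
#' For a clusters x sites table of cell counts, the expected count under the
#' chi-squared independence model is
#' `E(c, s) = rowtotal(c) * coltotal(s) / grandtotal`, and
#' `Ro/e = observed / expected` elementwise.  Values > 1 flag preferential
#' enrichment of a cluster in a site, < 1 depletion.  Entries with zero
#' expected count are reported as `NA` (undefined), not infinity.
#'
#' @param observed clusters x sites non-negative count matrix.
#' @return A list of class `tme_roe`: `roe`, `observed`, `expected`.
#' @examples
#' roe(matrix(c(10, 0, 0, 10), 2, 2))  # diagonal 2, off-diagonal 0
#' @export
roe <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) stopf("counts must be >= 0")
  total <- sum(observed)
  if (total <= 0) stopf("grand total must be > 0")
  expected <- outer(rowSums(observed), colSums(observed)) / total
  r <- observed / expected
  r[expected == 0] <- NA_real_
  dimnames(r) <- dimnames(observed)
  structure(list(roe = r, observed = observed, expected = expected),
            class = "tme_roe")
}

#' @export
print.tme_roe <- function(x, digits = 3, ...) {
  cat("<tme_roe> observed/expected enrichment (>1 enriched, <1 depleted)\n")
  print(round(x$roe, digits))
  invisible(x)
}

#' @export
plot.tme_roe <- function(x, ...) {
  m <- x$roe
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[nrow(m):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(33, "Blue-Red 2"), axes = FALSE,
                  xlab = "site", ylab = "cluster", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 1)
  invisible(x)
}

#' Construct a gene set
#'
#' @param name set name.
#' @param genes unique member gene ids.
#' @param alpha rank-weight exponent of the weighted ECDF (default 0.25).
#' @return list of class `tme_geneset`.
#' @export
gene_set <- function(name, genes, alpha = 0.25) {
  if (anyDuplicated(genes)) stopf("gene set members must be unique")
  if (alpha < 0) stopf("alpha must be >= 0")
  structure(list(name = name, genes = genes, alpha = alpha),
            class = "tme_geneset")
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: name, description, then member genes.
#'
#' @param path file path.
#' @param alpha rank-weight exponent attached to every set.
#' @return named list of [gene_set()]s.
#' @export
read_gmt <- function(path, alpha = 0.25) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    gene_set(f[1], unique(f[-(1:2)]), alpha)
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Barbie-style running-sum statistic per sample: genes are ranked by
#' expression (descending; ties get average ranks, expressed as rank values
#' `N .. 1`); walking down the ranking, the score is the sum over positions
#' of the difference between the `|rank|^alpha`-weighted ECDF of set members
#' and the unweighted ECDF of non-members.  Purely rank-based, hence
#' invariant under strictly monotone transforms of the expression values.
#'
#' @param expr genes x samples expression matrix.
#' @param set a [gene_set()] (or character vector of genes).
#' @param alpha rank-weight exponent; taken from the set when `NULL`.
#' @param normalize divide scores by their range across samples (GSVA's
#'   `ssgsea.norm`); default `FALSE` (raw running-sum score).
#' @return named numeric vector, one score per sample.
#' @export
ssgsea <- function(expr, set, alpha = NULL, normalize = FALSE) {
  if (is.character(set)) set <- gene_set("set", set)
  if (is.null(alpha)) alpha <- set$alpha
  expr <- as.matrix(expr)
  members <- rownames(expr) %in% set$genes
  if (!any(members))
    stopf("gene set '%s' has no member in the expression matrix", set$name)
  N <- nrow(expr)
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    # rank values: largest expression -> rank N; ties -> average rank
    rv <- rank(expr[, j], ties.method = "average")
    ord <- order(-rv, seq_len(N))  # walk from highest to lowest
    inset <- members[ord]
    w <- abs(rv[ord])^alpha
    w[!inset] <- 0
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inset) / sum(!inset)
    sum(p_in - p_out)
  }, numeric(1))
  out <- stats::setNames(scores, colnames(expr))
  if (normalize) {
    rng <- diff(range(out))
    if (rng > 0) out <- out / rng
  }
  out
}

#' Score a gene signature per cell
#'
#' `mean_z`: the average across signature genes of each gene's z-score over
#' cells (constant genes contribute 0).  `ssgsea`: delegates to [ssgsea()].
#' The default tissue-resident-macrophage (TRM) signature is available via
#' [trm_signature()].
#'
#' @param expr genes x cells expression matrix.
#' @param genes signature gene ids; members missing from the matrix are
#'   dropped with a warning, and an error is raised if none remain.
#' @param method `"mean_z"` (default) or `"ssgsea"`.
#' @param alpha rank-weight exponent for the ssgsea method.
#' @return numeric vector, one score per cell/sample.
#' @export
score_signature <- function(expr, genes, method = c("mean_z", "ssgsea"),
                            alpha = 0.25) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  present <- intersect(genes, rownames(expr))
  if (!length(present)) stopf("no signature gene present in the matrix")
  if (length(present) < length(genes))
    warnf("signature genes absent and dropped: %s",
          paste(setdiff(genes, present), collapse = ", "))
  if (method == "ssgsea")
    return(ssgsea(expr, gene_set("signature", present, alpha)))
  sub <- expr[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sds <- apply(sub, 1L, stats::sd)
  z <- (sub - mu) / ifelse(sds > 0, sds, 1)
  z[sds == 0, ] <- 0
  colMeans(z)
}

#' Default tissue-resident-macrophage signature
#'
#' Core TRM genes: TIMD4, LYVE1, FOLR2, CCR2 plus an MHC class II gene list.
#' `TIMD4` is the assumed intent of the commonly mis-typed "TIDM4"; pass
#' `timd4 = "TIDM4"` to use the literal symbol.  The MHC-II family is
#' expanded to a configurable default of HLA-DRA, HLA-DRB1, HLA-DPA1,
#' HLA-DPB1.
#'
#' @param mhc2 MHC class II gene symbols.
#' @param timd4 symbol to use for the TIMD4 member.
#' @return character vector of signature genes.
#' @export
trm_signature <- function(mhc2 = c("HLA-DRA", "HLA-DRB1", "HLA-DPA1", "HLA-DPB1"),
                          timd4 = "TIMD4") {
  c(timd4, "LYVE1", "FOLR2", "CCR2", mhc2)
}

#' Compare per-sample frequencies across sites
#'
#' For each feature column (e.g. phenotype or CN frequency per sample):
#' a two-sided Wilcoxon rank-sum test for 2 groups, Kruskal-Wallis for
#' more.  Rank-sum p-values are exact (full enumeration, tie-aware) when
#' both groups have <= 10 samples, normal approximation with tie correction
#' otherwise.  P-values are Benjamini-Hochberg adjusted across features.
#'
#' @param freqs samples x features numeric matrix (or data.frame).
#' @param groups factor/character of length `nrow(freqs)` (e.g. site).
#' @return data.frame `feature`, `test`, `statistic`, `p_value`, `p_adj`.
#' @export
compare_site_frequencies <- function(freqs, groups) {
  freqs <- as.matrix(freqs)
  groups <- as.factor(groups)
  if (length(groups) != nrow(freqs)) stopf("groups length must match rows of freqs")
  sizes <- table(groups)
  if (length(sizes) < 2L) stopf("need >= 2 groups")
  if (any(sizes == 0L)) stopf("group(s) with 0 samples: %s",
                              paste(names(sizes)[sizes == 0], collapse = ", "))
  two <- length(sizes) == 2L
  res <- lapply(seq_len(ncol(freqs)), function(j) {
    v <- freqs[, j]
    if (two) {
      g <- levels(groups)
      t <- rank_sum_test(v[groups == g[1]], v[groups == g[2]])
      data.frame(feature = colnames(freqs)[j] %||% j, test = "wilcoxon",
                 statistic = t$statistic, p_value = t$p.value)
    } else {
      k <- stats::kruskal.test(v, groups)
      data.frame(feature = colnames(freqs)[j] %||% j, test = "kruskal-wallis",
                 statistic = unname(k$statistic), p_value = k$p.value)
    }
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
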