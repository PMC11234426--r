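#' @keywords internal
"_PACKAGE"

# Percentile convention used throughout the package: linear interpolation
# between order statistics (stats::quantile type 7).
pctl <- function(x, p) stats::quantile(x, p / 100, type = 7, names = FALSE)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' 1 means identical partitions (up to label names), 0 is the expected
#' agreement of random partitions.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions have different lengths")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical in structure
  (nij - expected) / denom
}

# Exact or approximate two-sided rank-sum test.
#
# For n1, n2 <= max_exact the permutation distribution of the rank-sum of
# group 1 (average ranks, so ties are handled) is enumerated exhaustively;
# the two-sided p is P(|S - E| >= |s_obs - E|).  Larger groups fall back to
# the normal approximation with tie correction via stats::wilcox.test.
rank_sum_test <- function(x, y, max_exact = 10L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stopf("rank-sum test needs non-empty groups")
  r <- rank(c(x, y))
  s_obs <- sum(r[seq_len(n1)])
  if (n1 <= max_exact && n2 <= max_exact) {
    idx <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    e <- n1 * (n1 + n2 + 1) / 2
    d <- abs(s_obs - e)
    p <- mean(abs(sums - e) >= d - 1e-12)
    list(statistic = s_obs, p.value = p, exact = TRUE)
  } else {
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = s_obs, p.value = w$p.value, exact = FALSE)
  }
}

# k-means++ seeding (Arthur & Vassilvitskii) on rows of x; returns a
# k x ncol(x) matrix of initial centers.  Uses the current RNG stream.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = prob), ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

# Squared Euclidean cross-distances between rows of a and rows of b.
cross_dist2 <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# Relabel an integer/character cluster vector to contiguous ids 1..K ordered
# by decreasing cluster size (ties by first appearance).
relabel_by_size <- function(cl) {
  tab <- sort(table(cl), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(cl)])
}
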