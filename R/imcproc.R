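# IMC preprocessing: spillover compensation, hot-pixel removal, percentile
# contrast enhancement, nucleus-seeded segmentation with the 15-pixel
# artifact rule, and 99th-percentile single-cell quantification.
#
# Processing order is fixed: compensation -> denoise -> contrast ->
# segmentation -> quantification.

#' Compensate channel spillover
#'
#' Per pixel, recovers the non-negative source intensities x minimizing
#' ||x' S - observed'||2, where S\[i, j\] is the fraction of channel-i signal
#' detected in channel j.  Pixels whose unconstrained linear solve is already
#' non-negative are kept as-is; the rest are re-solved by non-negative least
#' squares.
#'
#' @param image a `tme_roi`.
#' @param spillover a [spillover_matrix()] of dimension equal to the panel.
#' @param max_condition condition-number threshold above which the matrix is
#'   rejected as ill-conditioned.
#' @return The compensated `tme_roi` (all intensities >= 0).
#' @export
compensate_spillover <- function(image, spillover, max_condition = 1e8) {
  C <- dim(image$pixels)[3]
  s <- unclass(spillover)
  if (nrow(s) != C || ncol(s) != C)
    stopf("spillover is %dx%d but image has %d channels", nrow(s), ncol(s), C)
  if (any(abs(diag(s) - 1) > 1e-12)) stopf("spillover diagonal must be 1")
  kap <- kappa(s, exact = TRUE)
  if (kap > max_condition) {
    # name the two most collinear columns for the error message
    cs <- s / sqrt(colSums(s^2)[col(s)] + 0)
    cc <- crossprod(sweep(s, 2, sqrt(colSums(s^2)), "/"))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    nm <- image$panel$marker[worst]
    stopf("spillover matrix is ill-conditioned (condition number %.3g); channels '%s' and '%s' are nearly collinear",
          kap, nm[1], nm[2])
  }
  flat <- matrix(image$pixels, ncol = C)
  # observed = x' S  per pixel  =>  solve t(S) %*% x = obs
  x <- t(solve(t(s), t(flat)))
  bad <- which(matrixRowMin(x) < -1e-10)
  for (r in bad) x[r, ] <- pracma::lsqnonneg(t(s), flat[r, ])$x
  x[x < 0] <- 0
  out <- image
  out$pixels <- array(x, dim = dim(image$pixels), dimnames = dimnames(image$pixels))
  out
}

matrixRowMin <- function(m) do.call(pmin, c(as.data.frame(m), list(na.rm = TRUE)))

# Median over the 3x3 window centred on each pixel (window clipped at the
# image borders, centre included).
median3x3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(NA_real_, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  shifts <- vector("list", 9L); k <- 1L
  for (di in 0:2) for (dj in 0:2) {
    shifts[[k]] <- as.vector(pad[di + seq_len(H), dj + seq_len(W)])
    k <- k + 1L
  }
  stack <- do.call(cbind, shifts)
  matrix(apply(stack, 1L, stats::median, na.rm = TRUE), H, W)
}

#' Remove hot pixels
#'
#' A hot pixel is a pixel exceeding the median of its 3x3 neighborhood
#' (centre included, clipped at image borders) by more than `threshold`;
#' it is replaced by that median.  All other pixels are unchanged.
#'
#' @param image a `tme_roi`.
#' @param threshold raw-count excess over the neighborhood median (default 50).
#' @return The denoised `tme_roi`.
#' @export
remove_hot_pixels <- function(image, threshold = 50) {
  if (threshold < 0) stopf("threshold must be >= 0")
  out <- image
  for (ch in seq_len(dim(image$pixels)[3])) {
    m <- image$pixels[, , ch]
    med <- median3x3(m)
    hot <- m > med + threshold
    m[hot] <- med[hot]
    out$pixels[, , ch] <- m
  }
  out
}

#' Percentile contrast enhancement
#'
#' Per channel, clips intensities to the \[`lower_pct`, `upper_pct`\]
#' percentile range and rescales linearly to \[0, 1\].  Monotone in the
#' input.  A degenerate channel (equal percentiles) is set to zero with a
#' warning.
#'
#' @param image a `tme_roi`.
#' @param lower_pct,upper_pct percentiles in \[0, 100\], lower < upper.
#' @return The rescaled `tme_roi`.
#' @export
enhance_contrast <- function(image, lower_pct = 0, upper_pct = 99) {
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100))
    stopf("need 0 <= lower_pct < upper_pct <= 100")
  out <- image
  for (ch in seq_len(dim(image$pixels)[3])) {
    m <- image$pixels[, , ch]
    lo <- pctl(m, lower_pct); hi <- pctl(m, upper_pct)
    if (hi <= lo) {
      warnf("channel '%s' is degenerate (p%g == p%g); set to zero",
            dimnames(image$pixels)[[3]][ch], lower_pct, upper_pct)
      out$pixels[, , ch] <- 0
    } else {
      out$pixels[, , ch] <- pmin(pmax((m - lo) / (hi - lo), 0), 1)
    }
  }
  out
}

# 8-connected components of a logical matrix; returns an integer label
# matrix (0 background, labels 1..N in raster-scan order of first pixel).
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (!length(idx)) return(lab)
  pos <- match(idx, idx)
  # edges to the 4 forward neighbors (E, SW, S, SE) suffice for undirected CC
  i <- ((idx - 1L) %% H) + 1L
  j <- ((idx - 1L) %/% H) + 1L
  edges <- list()
  for (d in list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))) {
    ni <- i + d[1]; nj <- j + d[2]
    ok <- ni >= 1L & ni <= H & nj >= 1L & nj <= W
    nidx <- (nj - 1L) * H + ni
    hit <- ok & !is.na(match(nidx, idx)) & mask[pmin(pmax(nidx, 1L), H * W)]
    edges[[length(edges) + 1L]] <- cbind(pos[hit], match(nidx[hit], idx))
  }
  e <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(rbind(e, cbind(seq_along(idx), seq_along(idx))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  # relabel in raster order of first occurrence
  first <- !duplicated(comp)
  map <- integer(max(comp)); map[comp[first]] <- seq_len(sum(first))
  lab[idx] <- map[comp]
  lab
}

component_centroids <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) return(cbind(x = numeric(0), y = numeric(0)))
  H <- nrow(lab)
  i <- ((idx - 1L) %% H) + 1L; j <- ((idx - 1L) %/% H) + 1L
  f <- factor(lab[idx], levels = seq_len(max(lab)))
  # pixel (i, j) has center (x = j-1, y = i-1)
  cbind(x = as.vector(tapply(j - 1, f, mean)), y = as.vector(tapply(i - 1, f, mean)))
}

#' Segment cells from the nucleus channel
#'
#' The nucleus channel is thresholded; 8-connected components become cell
#' seeds, each expanded to a whole-cell footprint by fixed-radius dilation
#' (pixels within `cell_radius` of any nucleus pixel, contested pixels going
#' to the seed with the nearer nucleus centroid, ties to the lower label id).
#' Connected components in membrane/lineage channels are then either merged
#' into the nearest cell (centroid-to-centroid distance <= `distance_limit`)
#' or discarded as acquisition artifacts beyond that distance.
#'
#' @param image a `tme_roi` (preprocessed).
#' @param nucleus_threshold intensity threshold for nucleus foreground.
#' @param distance_limit artifact rule: maximum distance (pixels) from a
#'   non-nucleus component's centroid to the nearest nucleus centroid
#'   (default 15).
#' @param cell_radius whole-cell expansion radius in pixels.
#' @param signal_threshold foreground threshold for membrane/lineage
#'   channels (defaults to `nucleus_threshold`).
#' @return A `tme_mask`: integer H x W matrix, 0 = background, labels 1..N;
#'   attribute `centroids` holds the nucleus centroids.
#' @export
segment_cells <- function(image, nucleus_threshold, distance_limit = 15,
                          cell_radius = 7, signal_threshold = nucleus_threshold) {
  if (distance_limit < 0) stopf("distance_limit must be >= 0")
  nuc <- nucleus_channel(image$panel)
  nm <- image$pixels[, , nuc]
  H <- nrow(nm); W <- ncol(nm)
  seeds <- label_components(nm > nucleus_threshold)
  n_seed <- max(seeds)
  if (n_seed == 0L)
    return(structure(matrix(0L, H, W), centroids = cbind(x = numeric(0), y = numeric(0)),
                     class = "tme_mask"))
  cents <- component_centroids(seeds)

  # fixed-radius dilation with nearest-centroid tie-breaking
  lab <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  Hs <- nrow(seeds)
  for (k in seq_len(n_seed)) {
    idx <- which(seeds == k)
    si <- ((idx - 1L) %% Hs) + 1L; sj <- ((idx - 1L) %/% Hs) + 1L
    ir <- max(1L, min(si) - ceiling(cell_radius)):min(H, max(si) + ceiling(cell_radius))
    jr <- max(1L, min(sj) - ceiling(cell_radius)):min(W, max(sj) + ceiling(cell_radius))
    g <- as.matrix(expand.grid(i = ir, j = jr))
    # distance from each candidate pixel to the nearest nucleus pixel of seed k
    d2 <- cross_dist2(cbind(g[, "j"] - 1, g[, "i"] - 1), cbind(sj - 1, si - 1))
    dmin <- sqrt(apply(d2, 1L, min))
    inside <- dmin <= cell_radius
    gi <- g[inside, , drop = FALSE]
    dcent <- sqrt((gi[, "j"] - 1 - cents[k, "x"])^2 + (gi[, "i"] - 1 - cents[k, "y"])^2)
    lin <- (gi[, "j"] - 1L) * H + gi[, "i"]
    take <- dcent < bestd[lin] |
      (abs(dcent - bestd[lin]) < 1e-12 & lab[lin] > k)
    lab[lin[take]] <- k
    bestd[lin[take]] <- dcent[take]
  }

  # artifact rule on membrane/lineage channels
  other <- which(image$panel$role %in% c("membrane", "lineage"))
  for (ch in other) {
    comp <- label_components(image$pixels[, , ch] > signal_threshold & lab == 0L)
    if (max(comp) == 0L) next
    cc <- component_centroids(comp)
    for (k in seq_len(max(comp))) {
      d <- sqrt((cents[, "x"] - cc[k, "x"])^2 + (cents[, "y"] - cc[k, "y"])^2)
      nearest <- which.min(d)
      if (d[nearest] <= distance_limit) {
        idx <- which(comp == k)
        free <- idx[lab[idx] == 0L]
        lab[free] <- nearest
      }
      # else: artifact, discarded
    }
  }

  structure(lab, centroids = cents, class = "tme_mask")
}

#' @export
print.tme_mask <- function(x, ...) {
  cat(sprintf("<tme_mask> %d x %d px, %d cells\n", nrow(x), ncol(x),
              max(0L, max(x))))
  invisible(x)
}

#' Quantify single cells from a segmentation mask
#'
#' Per cell and channel, the mean intensity over the cell footprint; each
#' channel is then normalized by its `norm_pct` percentile across cells
#' (linear-interpolation percentile) and clipped to \[0, 1\].  Centroids are
#' unweighted means of member pixel coordinates.
#'
#' @param image a `tme_roi`.
#' @param mask a `tme_mask` of matching size.
#' @param norm_pct normalization percentile (default 99).
#' @return A `data.frame` (class `tme_cells`): `cell_id`, `roi_id`, `site`,
#'   `x`, `y`, `area`, one column per marker with normalized means in
#'   \[0, 1\].  Attributes: `markers`, `pixel_size`, `roi_dims` (H, W).
#' @export
quantify_cells <- function(image, mask, norm_pct = 99) {
  if (!all(dim(mask) == dim(image$pixels)[1:2]))
    stopf("mask dimensions do not match image")
  n <- max(0L, max(mask))
  markers <- image$panel$marker
  if (n == 0L) {
    out <- cbind(data.frame(cell_id = integer(0), roi_id = character(0),
                            site = character(0), x = numeric(0), y = numeric(0),
                            area = numeric(0)),
                 stats::setNames(as.data.frame(matrix(numeric(0), 0, length(markers))),
                                 markers))
    return(as_tme_cells(out, markers, image))
  }
  idx <- which(mask > 0)
  lab <- mask[idx]
  H <- nrow(mask)
  i <- ((idx - 1L) %% H) + 1L; j <- ((idx - 1L) %/% H) + 1L
  f <- factor(lab, levels = seq_len(n))
  area <- as.vector(table(f))
  cx <- as.vector(tapply(j - 1, f, mean)); cy <- as.vector(tapply(i - 1, f, mean))
  raw <- matrix(0, n, length(markers), dimnames = list(NULL, markers))
  for (ch in seq_along(markers)) {
    v <- image$pixels[, , ch][idx]
    raw[, ch] <- as.vector(tapply(v, f, mean))
  }
  norm <- raw
  for (ch in seq_along(markers)) {
    p <- pctl(raw[, ch], norm_pct)
    norm[, ch] <- if (p > 0) pmin(raw[, ch] / p, 1) else 0
  }
  out <- cbind(data.frame(cell_id = seq_len(n), roi_id = image$roi_id,
                          site = image$site, x = as.numeric(cx),
                          y = as.numeric(cy), area = area,
                          stringsAsFactors = FALSE),
               as.data.frame(norm))
  as_tme_cells(out, markers, image)
}

as_tme_cells <- function(df, markers, image = NULL) {
  attr(df, "markers") <- markers
  if (!is.null(image)) {
    attr(df, "pixel_size") <- image$pixel_size
    attr(df, "roi_dims") <- dim(image$pixels)[1:2]
  }
  class(df) <- c("tme_cells", "data.frame")
  df
}

#' Extract the marker matrix from a cell table
#' @param cells a `tme_cells` table.
#' @return numeric cells x markers matrix.
#' @export
marker_matrix <- function(cells) {
  as.matrix(cells[, attr(cells, "markers"), drop = FALSE])
}
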