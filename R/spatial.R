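# Spatial topology: per-image kNN cell graphs, cellular-neighborhood (CN)
# composition and k-means motifs, permutation-null interaction/avoidance
# classification, and density-based detection of TLS-like patches.

#' Build per-image neighbor graphs
#'
#' Exact Euclidean k-nearest neighbors (ties broken by cell order) or
#' fixed-radius neighbors, computed within each image separately so
#' neighbors never cross image boundaries.
#'
#' @param cells a cell table with `x`, `y` and `roi_id` columns
#'   (a `tme_cells` or any data.frame).
#' @param mode `"knn"` (default) or `"radius"`.
#' @param k neighbors per cell (default 20, the CN window used throughout).
#' @param r radius for `mode = "radius"`, in the same units as `x`/`y`.
#' @return A list of class `tme_graph`: `neighbors` (list of integer row
#'   indices into `cells`, per cell), `mode`, `k`/`r`, `roi_id`.
#' @export
build_graph <- function(cells, mode = c("knn", "radius"), k = 20, r = NULL) {
  mode <- match.arg(mode)
  n <- nrow(cells)
  roi <- if ("roi_id" %in% names(cells)) as.character(cells$roi_id) else rep("roi", n)
  nb <- vector("list", n)
  for (im in unique(roi)) {
    idx <- which(roi == im)
    m <- length(idx)
    if (mode == "knn") {
      if (m < 2L) stopf("image '%s' has %d cell(s); knn needs >= 2", im, m)
      kk <- k
      if (kk >= m) {
        warnf("image '%s': k = %d >= %d cells; capped at %d", im, k, m, m - 1L)
        kk <- m - 1L
      }
      d2 <- cross_dist2(cbind(cells$x[idx], cells$y[idx]),
                        cbind(cells$x[idx], cells$y[idx]))
      for (a in seq_len(m)) {
        o <- order(d2[a, -a])
        nb[[idx[a]]] <- idx[-a][o][seq_len(kk)]
      }
    } else {
      if (is.null(r) || r <= 0) stopf("radius mode needs r > 0")
      d2 <- cross_dist2(cbind(cells$x[idx], cells$y[idx]),
                        cbind(cells$x[idx], cells$y[idx]))
      for (a in seq_len(m))
        nb[[idx[a]]] <- idx[which(d2[a, ] <= r^2 & seq_len(m) != a)]
    }
  }
  structure(list(neighbors = nb, mode = mode, k = k, r = r, roi_id = roi),
            class = "tme_graph")
}

#' @export
print.tme_graph <- function(x, ...) {
  cat(sprintf("<tme_graph> %d cells, %d image(s), mode %s (%s)\n",
              length(x$neighbors), length(unique(x$roi_id)), x$mode,
              if (x$mode == "knn") paste0("k = ", x$k) else paste0("r = ", x$r)))
  invisible(x)
}

#' Graph edge list
#' @param graph a `tme_graph`.
#' @return data.frame `from`, `to` (directed, row indices).
#' @export
graph_edges <- function(graph) {
  data.frame(from = rep(seq_along(graph$neighbors),
                        lengths(graph$neighbors)),
             to = unlist(graph$neighbors))
}

#' Cellular-neighborhood composition
#'
#' Per cell, the fraction of each category among the window formed by the
#' center cell and its k nearest neighbors (k + 1 cells; set
#' `include_center = FALSE` for a neighbors-only window).  Categories are
#' the phenotypes, optionally including pseudo-cells such as "collagen I".
#'
#' @param cells cell table with a `phenotype` column.
#' @param graph a [build_graph()] result on the same table.
#' @param categories category levels; defaults to the phenotypes present.
#'   An error is raised if a cell's phenotype is not among them.
#' @param include_center include the center cell in its own window
#'   (default `TRUE`).
#' @return cells x categories matrix; rows sum to 1.
#' @export
cn_compose <- function(cells, graph, categories = NULL, include_center = TRUE) {
  phen <- as.character(cells$phenotype)
  if (is.null(categories)) categories <- sort(unique(phen))
  unknown <- setdiff(unique(phen), categories)
  if (length(unknown)) stopf("unknown category label(s): %s",
                             paste(unknown, collapse = ", "))
  n <- nrow(cells)
  comp <- matrix(0, n, length(categories), dimnames = list(NULL, categories))
  pf <- factor(phen, levels = categories)
  for (i in seq_len(n)) {
    win <- if (include_center) c(i, graph$neighbors[[i]]) else graph$neighbors[[i]]
    if (!length(win)) stopf("cell %d has no neighbors", i)
    comp[i, ] <- tabulate(pf[win], nbins = length(categories)) / length(win)
  }
  comp
}

#' Cluster neighborhood compositions into CN motifs
#'
#' K-means on the composition simplex with k-means++ seeding, `n_init`
#' restarts under a fixed seed, keeping the lowest within-cluster sum of
#' squares.  CN ids are relabeled by decreasing size.
#'
#' @param compositions cells x categories matrix from [cn_compose()].
#' @param k_cn number of cellular neighborhoods (default 15).
#' @param seed RNG seed.
#' @param n_init number of k-means++ restarts.
#' @param iter_max Lloyd iterations per restart.
#' @return A list of class `tme_cn`: `cn` (integer per cell), `centroids`
#'   (k_cn x categories, rows sum to 1), `withinss`.
#' @export
cn_cluster <- function(compositions, k_cn = 15, seed = 1L, n_init = 10L,
                       iter_max = 100L) {
  x <- as.matrix(compositions)
  n_distinct <- nrow(unique(x))
  if (k_cn > n_distinct)
    stopf("k_cn = %d exceeds the %d distinct composition rows", k_cn, n_distinct)
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_init)) {
    init <- kmeanspp_centers(x, k_cn)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = iter_max, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  memb <- relabel_by_size(best$cluster)
  cents <- do.call(rbind, lapply(seq_len(k_cn), function(k)
    colMeans(x[memb == k, , drop = FALSE])))
  colnames(cents) <- colnames(x)
  structure(list(cn = memb, centroids = cents,
                 withinss = best$tot.withinss, k_cn = k_cn, seed = seed),
            class = "tme_cn")
}

#' @export
print.tme_cn <- function(x, ...) {
  cat(sprintf("<tme_cn> %d cells in %d cellular neighborhoods\n",
              length(x$cn), x$k_cn))
  dom <- colnames(x$centroids)[apply(x$centroids, 1L, which.max)]
  print(data.frame(cn = seq_len(x$k_cn), n = tabulate(x$cn, x$k_cn),
                   dominant = dom))
  invisible(x)
}

# Per-image neighbor-count statistic for every ordered phenotype pair:
# observed(A, B) = mean over A-cells of the number of B cells among their
# neighbors.  Returns a phenotypes x phenotypes matrix.
pair_stat <- function(counts, labels, levels) {
  t(vapply(levels, function(a) {
    rows <- labels == a
    if (!any(rows)) rep(NA_real_, length(levels))
    else colMeans(counts[rows, , drop = FALSE])
  }, numeric(length(levels))))
}

#' Permutation test for spatial interaction and avoidance
#'
#' Per image and ordered phenotype pair (A, B), the observed statistic is
#' the mean number of B neighbors per A cell.  The null keeps the graph
#' fixed and permutes phenotype labels over the cells of that image
#' (matched randomized tissue).  Add-one permutation p-values:
#' `p_interact = (1 + #\{perm >= obs\}) / (n_perm + 1)` and `p_avoid`
#' analogously with `<=`.  A pair is classified `interaction` when
#' `p_interact <= alpha`, else `avoidance` when `p_avoid <= alpha`, else
#' `none`; pairs whose phenotype is absent from an image are recorded as
#' `absent`.
#'
#' @param cells cell table with `phenotype` (and `roi_id`).
#' @param graph a [build_graph()] result.
#' @param n_perm number of permutations (default 1000, minimum 100).
#' @param alpha classification level (default 0.01).
#' @param seed RNG seed.
#' @return data.frame of class `tme_interaction`: `roi_id`, `from`, `to`,
#'   `observed`, `p_interact`, `p_avoid`, `classification`, `n_perm`.
#' @export
interaction_test <- function(cells, graph, n_perm = 1000, alpha = 0.01,
                             seed = 1L) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  phen <- as.character(cells$phenotype)
  levels_all <- sort(unique(phen))
  roi <- graph$roi_id
  set.seed(seed)
  res <- list()
  for (im in unique(roi)) {
    idx <- which(roi == im)
    m <- length(idx)
    lab <- phen[idx]
    lv <- sort(unique(lab))
    # adjacency (directed kNN) restricted to the image, as sparse matrix
    nb <- graph$neighbors[idx]
    loc <- match(unlist(nb), idx)
    A <- Matrix::sparseMatrix(i = rep(seq_len(m), lengths(nb)), j = loc,
                              x = 1, dims = c(m, m))
    L <- 1 * outer(lab, lv, "==")
    colnames(L) <- lv
    counts <- as.matrix(A %*% L)      # cell x phenotype neighbor counts
    obs <- pair_stat(counts, lab, lv)
    ge <- matrix(0L, length(lv), length(lv)); le <- ge
    for (p in seq_len(n_perm)) {
      per <- sample.int(m)
      labp <- lab[per]
      cp <- as.matrix(A %*% L[per, , drop = FALSE])
      st <- pair_stat(cp, labp, lv)
      ge <- ge + (st >= obs - 1e-12)
      le <- le + (st <= obs + 1e-12)
    }
    p_int <- (1 + ge) / (n_perm + 1)
    p_avd <- (1 + le) / (n_perm + 1)
    cls <- ifelse(p_int <= alpha, "interaction",
                  ifelse(p_avd <= alpha, "avoidance", "none"))
    grid <- expand.grid(from = lv, to = lv, stringsAsFactors = FALSE)
    part <- data.frame(roi_id = im, from = grid$from, to = grid$to,
                       observed = obs[cbind(match(grid$from, lv), match(grid$to, lv))],
                       p_interact = p_int[cbind(match(grid$from, lv), match(grid$to, lv))],
                       p_avoid = p_avd[cbind(match(grid$from, lv), match(grid$to, lv))],
                       classification = cls[cbind(match(grid$from, lv), match(grid$to, lv))],
                       n_perm = n_perm, stringsAsFactors = FALSE)
    # phenotypes present globally but absent from this image
    missing_lv <- setdiff(levels_all, lv)
    if (length(missing_lv)) {
      gm <- expand.grid(from = levels_all, to = levels_all, stringsAsFactors = FALSE)
      gm <- gm[gm$from %in% missing_lv | gm$to %in% missing_lv, ]
      if (nrow(gm))
        part <- rbind(part, data.frame(roi_id = im, from = gm$from, to = gm$to,
                                       observed = NA_real_, p_interact = NA_real_,
                                       p_avoid = NA_real_, classification = "absent",
                                       n_perm = n_perm, stringsAsFactors = FALSE))
    }
    res[[length(res) + 1L]] <- part
  }
  out <- do.call(rbind, res)
  class(out) <- c("tme_interaction", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

# Brute-force reference for the interaction statistic: double loop over all
# ordered cell pairs, recomputing each cell's k nearest neighbors by sorting
# its distance row.  Intended for small images and testing.
interaction_stat_bruteforce <- function(cells, k) {
  phen <- as.character(cells$phenotype)
  lv <- sort(unique(phen))
  n <- nrow(cells)
  cnt <- matrix(0, n, length(lv), dimnames = list(NULL, lv))
  for (i in seq_len(n)) {
    d <- sqrt((cells$x - cells$x[i])^2 + (cells$y - cells$y[i])^2)
    d[i] <- Inf
    ord <- order(d, seq_len(n))[seq_len(min(k, n - 1L))]
    for (j in ord) cnt[i, phen[j]] <- cnt[i, phen[j]] + 1
  }
  pair_stat(cnt, phen, lv)
}

#' Detect TLS-like patches of target cells
#'
#' Density-based spatial clustering (DBSCAN semantics) over the cells whose
#' phenotype belongs to `target_phenotypes`: a core point has at least
#' `min_size` target cells (itself included) within `eps`; core points
#' within `eps` of each other share a patch; border cells are attached to
#' the first core patch reaching them in cell-id order.  Patch area is the
#' convex hull of member centroids; per-image patch density is
#' patches / ROI area in mm^2.
#'
#' @param cells cell table (`x`, `y` in pixels, `phenotype`, `roi_id`).
#' @param target_phenotypes phenotypes forming patches (default the TLS
#'   compartment: B cells and memory CD4 T cells).
#' @param eps neighborhood radius in microns (default 20).
#' @param min_size minimum target cells within `eps` for a core point
#'   (default 20).
#' @param pixel_size microns per pixel; taken from the cell-table attribute
#'   when present (default 1).
#' @param roi_area_mm2 named vector of image areas in mm^2 for the density
#'   denominator; derived from the `roi_dims` attribute when available.
#' @return A list of class `tme_patches`: `patches` (data.frame `patch_id`,
#'   `roi_id`, `n_cells`, `area_um2`), `membership` (patch id per row of
#'   `cells`, 0 = none), `density` (patches per mm^2 per image),
#'   `composition` (patch x phenotype fractions).
#' @export
detect_patches <- function(cells,
                           target_phenotypes = c("B", "CD4 T memory"),
                           eps = 20, min_size = 20, pixel_size = NULL,
                           roi_area_mm2 = NULL) {
  if (eps <= 0) stopf("eps must be > 0")
  if (min_size < 1) stopf("min_size must be >= 1")
  if (is.null(pixel_size))
    pixel_size <- attr(cells, "pixel_size") %||% 1
  roi <- if ("roi_id" %in% names(cells)) as.character(cells$roi_id)
         else rep("roi", nrow(cells))
  membership <- integer(nrow(cells))
  patches <- list()
  density <- numeric(0)
  next_id <- 0L
  for (im in unique(roi)) {
    tcells <- which(roi == im & cells$phenotype %in% target_phenotypes)
    n_before <- next_id
    if (length(tcells)) {
      xy <- cbind(cells$x[tcells], cells$y[tcells]) * pixel_size
      d2 <- cross_dist2(xy, xy)
      nbh <- lapply(seq_along(tcells), function(a) which(d2[a, ] <= eps^2))
      core <- lengths(nbh) >= min_size  # neighborhood includes the point itself
      lab <- integer(length(tcells))
      for (a in order(tcells)) {        # cell-id order
        if (!core[a] || lab[a] != 0L) next
        next_id <- next_id + 1L
        queue <- a; lab[a] <- next_id
        while (length(queue)) {
          q <- queue[1]; queue <- queue[-1]
          for (b in nbh[[q]]) {
            if (lab[b] == 0L) {
              lab[b] <- next_id
              if (core[b]) queue <- c(queue, b)
            }
          }
        }
      }
      membership[tcells] <- lab
    }
    ids <- if (next_id > n_before) (n_before + 1L):next_id else integer(0)
    for (pid in ids) {
      mem <- which(membership == pid)
      xy <- cbind(cells$x[mem], cells$y[mem]) * pixel_size
      patches[[length(patches) + 1L]] <-
        data.frame(patch_id = pid, roi_id = im, n_cells = length(mem),
                   area_um2 = hull_area(xy), stringsAsFactors = FALSE)
    }
    area <- if (!is.null(roi_area_mm2)) roi_area_mm2[[im]]
            else {
              dims <- attr(cells, "roi_dims")
              if (!is.null(dims)) prod(dims) * pixel_size^2 / 1e6 else NA_real_
            }
    density[im] <- length(ids) / area
  }
  ptab <- if (length(patches)) do.call(rbind, patches)
          else data.frame(patch_id = integer(0), roi_id = character(0),
                          n_cells = integer(0), area_um2 = numeric(0))
  comp <- patch_composition(membership, cells$phenotype)
  structure(list(patches = ptab, membership = membership, density = density,
                 composition = comp, eps = eps, min_size = min_size,
                 target_phenotypes = target_phenotypes),
            class = "tme_patches")
}

hull_area <- function(xy) {
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

patch_composition <- function(membership, phenotype) {
  ids <- sort(unique(membership[membership > 0]))
  lv <- sort(unique(as.character(phenotype)))
  comp <- matrix(0, length(ids), length(lv), dimnames = list(ids, lv))
  for (r in seq_along(ids)) {
    tab <- table(factor(phenotype[membership == ids[r]], levels = lv))
    comp[r, ] <- as.numeric(tab) / sum(tab)
  }
  comp
}

#' @export
print.tme_patches <- function(x, ...) {
  cat(sprintf("<tme_patches> %d patch(es) (eps = %g um, min_size = %d)\n",
              nrow(x$patches), x$eps, x$min_size))
  if (nrow(x$patches)) print(x$patches)
  invisible(x)
}

#' Per-patch composition and marker profile
#'
#' Per patch: phenotype fractions over member cells (sum to 1) and, for each
#' requested marker, the mean normalized expression over member cells,
#' optionally restricted to a phenotype filter (e.g. an exhaustion marker
#' over T cells only).
#'
#' @param patch_set a [detect_patches()] result.
#' @param cells the cell table the patches were detected on.
#' @param markers marker column names to average; an absent marker is an
#'   error.
#' @param phenotype_filter optional phenotypes the marker means are
#'   restricted to.
#' @return data.frame, one row per patch: `patch_id`, `n_cells`, phenotype
#'   fractions (`frac_*`) and marker means (`mean_*`).
#' @export
patch_profile <- function(patch_set, cells, markers = character(0),
                          phenotype_filter = NULL) {
  absent <- setdiff(markers, names(cells))
  if (length(absent)) stopf("marker(s) absent from cell table: %s",
                            paste(absent, collapse = ", "))
  ids <- sort(unique(patch_set$membership[patch_set$membership > 0]))
  lv <- sort(unique(as.character(cells$phenotype)))
  rows <- lapply(ids, function(pid) {
    mem <- which(patch_set$membership == pid)
    fr <- table(factor(cells$phenotype[mem], levels = lv))
    fr <- as.numeric(fr) / sum(fr)
    row <- data.frame(patch_id = pid, n_cells = length(mem))
    for (i in seq_along(lv)) row[[paste0("frac_", lv[i])]] <- fr[i]
    sel <- if (is.null(phenotype_filter)) mem
           else mem[cells$phenotype[mem] %in% phenotype_filter]
    for (mk in markers)
      row[[paste0("mean_", mk)]] <- if (length(sel)) mean(cells[[mk]][sel]) else NA_real_
    row
  })
  if (!length(rows))
    return(data.frame(patch_id = integer(0), n_cells = integer(0)))
  do.call(rbind, rows)
}
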