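# Synthetic multiplexed-imaging and single-cell data with planted ground truth.
#
# The generator emulates the structure of an IMC + single-nucleus RNA study of
# primary and metastatic lung adenocarcinoma: multi-channel ROIs with nucleus /
# membrane / lineage / structure channels, spillover and hot-pixel noise,
# site-specific phenotype composition, TLS-like cell aggregates, and
# negative-binomial gene-by-cell count matrices with marker genes,
# mitochondrial content and doublets.  Every artifact carries its ground truth
# so downstream statistics can be scored exactly.

#' Construct an antibody panel
#'
#' A panel is an ordered set of channels, each a (marker, role) pair. Roles
#' follow IMC practice: exactly one `nucleus` channel (e.g. an iridium
#' intercalator), plus `membrane`, `lineage` and `structure` (e.g. collagen I)
#' channels.
#'
#' @param markers character vector of unique channel/marker names.
#' @param roles character vector, same length, each one of
#'   `"nucleus"`, `"membrane"`, `"lineage"`, `"structure"`.
#' @return A `data.frame` with columns `marker` and `role`, class `tme_panel`.
#' @examples
#' imc_panel(c("DNA1", "CD20", "CD4", "CollagenI"),
#'           c("nucleus", "lineage", "lineage", "structure"))
#' @export
imc_panel <- function(markers, roles) {
  roles <- match.arg(roles, c("nucleus", "membrane", "lineage", "structure"),
                     several.ok = TRUE)
  if (length(markers) != length(roles)) stopf("markers and roles differ in length")
  if (anyDuplicated(markers)) stopf("channel names must be unique")
  if (sum(roles == "nucleus") != 1L) stopf("panel must have exactly one nucleus channel")
  structure(data.frame(marker = markers, role = roles,
                       stringsAsFactors = FALSE),
            class = c("tme_panel", "data.frame"))
}

nucleus_channel <- function(panel) which(panel$role == "nucleus")

#' Construct a spillover matrix
#'
#' Entry (i, j) is the fraction of channel-i signal detected in channel j.
#' The diagonal is 1; off-diagonal entries lie in \[0, 1).
#'
#' @param n number of channels (identity spillover), or ignored when `mat`
#'   is given.
#' @param mat optional full square matrix to validate and use.
#' @param channels optional channel names for dimnames.
#' @return A square matrix of class `tme_spillover`.
#' @export
spillover_matrix <- function(n = NULL, mat = NULL, channels = NULL) {
  if (is.null(mat)) mat <- diag(n)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stopf("spillover matrix must be square")
  if (any(abs(diag(mat) - 1) > 1e-12)) stopf("spillover diagonal must be 1")
  off <- mat[row(mat) != col(mat)]
  if (any(off < 0 | off >= 1)) stopf("off-diagonal spillover must be in [0, 1)")
  if (!is.null(channels)) dimnames(mat) <- list(channels, channels)
  structure(mat, class = c("tme_spillover", "matrix"))
}

#' Random valid spillover matrix
#'
#' Diagonal 1 with independent uniform off-diagonal entries, emulating the
#' small channel crosstalk of metal isotope reporters.
#'
#' @param n channels; `max_spill` upper bound for off-diagonal entries.
#' @param max_spill maximum off-diagonal spill fraction.
#' @return A `tme_spillover` matrix.
#' @export
random_spillover <- function(n, max_spill = 0.2) {
  s <- matrix(stats::runif(n * n, 0, max_spill), n, n)
  diag(s) <- 1
  spillover_matrix(mat = s)
}

#' Generate a planted spatial cell layout
#'
#' Places `n_cells` background cells by rejection sampling with a minimum
#' pairwise centroid separation, draws their phenotypes from `composition`,
#' and plants optional disk aggregates (TLS-like structures) whose member
#' centroids are uniform within the disk.  The RNG policy is: `set.seed(seed)`,
#' then (1) background phenotypes via a single `sample()` over the composition,
#' (2) background positions, (3) aggregate member positions in list order, so
#' the phenotype draw is reproducible by an independent oracle.
#'
#' @param n_cells number of background (non-aggregate) cells.
#' @param composition named numeric vector of phenotype probabilities
#'   (sums to 1).
#' @param width,height field size in pixels; geometry is half-open
#'   \[0, W) x \[0, H), origin top-left, x = column, y = row.
#' @param aggregates list of specs, each
#'   `list(center = c(x, y), radius, n, phenotype)`; `phenotype` may be a
#'   single label or a named probability vector; an optional `min_sep`
#'   overrides the aggregate-internal separation (default `min(min_sep, 2)`,
#'   since lymphoid aggregates are much denser than the surrounding tissue).
#' @param min_sep minimum centroid separation in pixels (default 10, twice
#'   the default nucleus radius, so segmentation ground truth is unambiguous).
#' @param site site label attached to all cells.
#' @param seed integer RNG seed, recorded in the ground truth.
#' @param max_tries rejection-sampling attempts per cell before declaring the
#'   packing infeasible.
#' @return A list of class `tme_layout`: `cells` (data.frame `cell_id`, `x`,
#'   `y`, `phenotype`, `aggregate`, `site`) and `ground_truth` (phenotypes,
#'   centroids, aggregate specs, composition, seed).
#' @export
generate_layout <- function(n_cells, composition, width = 500, height = 500,
                            aggregates = list(), min_sep = 10, site = "site1",
                            seed = 1L, max_tries = 200L) {
  if (abs(sum(composition) - 1) > 1e-9 && n_cells > 0)
    stopf("composition probabilities must sum to 1 (got %g)", sum(composition))
  if (width <= 0 || height <= 0) stopf("field dimensions must be positive")
  for (a in aggregates) if (a$radius <= 0) stopf("aggregate radii must be > 0")

  set.seed(seed)
  phen <- if (n_cells > 0)
    sample(names(composition), n_cells, replace = TRUE, prob = composition)
  else character(0)

  xs <- numeric(0); ys <- numeric(0)
  place <- function(propose, n_new, sep) {
    for (i in seq_len(n_new)) {
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        p <- propose()
        if (length(xs) == 0 ||
            min((xs - p[1])^2 + (ys - p[2])^2) >= sep^2) {
          xs <<- c(xs, p[1]); ys <<- c(ys, p[2]); ok <- TRUE; break
        }
      }
      if (!ok) stopf("infeasible packing: could not place cell %d of %d at min_sep %g after %d tries",
                     i, n_new, sep, max_tries)
    }
  }

  place(function() c(stats::runif(1, 0, width), stats::runif(1, 0, height)),
        n_cells, min_sep)
  agg_id <- rep(0L, n_cells)
  for (ai in seq_along(aggregates)) {
    a <- aggregates[[ai]]
    # aggregates are dense by nature; they use their own (smaller) separation
    sep_a <- if (!is.null(a$min_sep)) a$min_sep else min(min_sep, 2)
    place(function() {
      r <- a$radius * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
      c(a$center[1] + r * cos(th), a$center[2] + r * sin(th))
    }, a$n, sep_a)
    ap <- if (is.character(a$phenotype) && length(a$phenotype) == 1L)
      rep(a$phenotype, a$n)
    else sample(names(a$phenotype), a$n, replace = TRUE, prob = a$phenotype)
    phen <- c(phen, ap)
    agg_id <- c(agg_id, rep(ai, a$n))
  }

  cells <- data.frame(cell_id = seq_along(xs), x = xs, y = ys,
                      phenotype = phen, aggregate = agg_id,
                      site = rep_len(site, length(xs)),
                      stringsAsFactors = FALSE)
  gt <- list(phenotype = phen, centroid = cbind(x = xs, y = ys),
             aggregates = aggregates, composition = as.list(composition),
             site = site, seed = seed, min_sep = min_sep,
             width = width, height = height)
  structure(list(cells = cells, ground_truth = gt), class = "tme_layout")
}

#' Default per-phenotype marker intensity profiles
#'
#' One dominant lineage marker per phenotype at `hi`, all other non-nucleus
#' channels at `lo`; the nucleus channel is set for every cell at render time.
#'
#' @param panel a [imc_panel()].
#' @param phenotypes phenotype labels; by default one per non-nucleus,
#'   non-structure channel.
#' @param hi,lo high/low mean ion counts per pixel.
#' @return phenotype x channel matrix of mean intensities.
#' @export
default_profiles <- function(panel, phenotypes = NULL, hi = 10, lo = 0.1) {
  lin <- which(panel$role %in% c("membrane", "lineage", "structure"))
  if (is.null(phenotypes)) phenotypes <- panel$marker[lin]
  prof <- matrix(lo, length(phenotypes), nrow(panel),
                 dimnames = list(phenotypes, panel$marker))
  prof[, nucleus_channel(panel)] <- 0
  for (i in seq_along(phenotypes)) {
    ch <- lin[((i - 1L) %% length(lin)) + 1L]
    prof[i, ch] <- hi
  }
  prof
}

rasterize_disk <- function(cx, cy, radius, width, height) {
  # pixel (row i, col j), 1-based, has center (x = j-1, y = i-1)
  jr <- max(1L, floor(cx - radius) + 1L):min(width, ceiling(cx + radius) + 1L)
  ir <- max(1L, floor(cy - radius) + 1L):min(height, ceiling(cy + radius) + 1L)
  if (length(jr) == 0 || length(ir) == 0) return(cbind(i = integer(0), j = integer(0)))
  g <- expand.grid(i = ir, j = jr)
  keep <- (g$j - 1 - cx)^2 + (g$i - 1 - cy)^2 <= radius^2
  cbind(i = g$i[keep], j = g$j[keep])
}

#' Render a synthetic multiplexed ROI image
#'
#' Emulates IMC acquisition of a planted layout: each cell contributes a
#' nucleus disk on the nucleus channel and its phenotype's profile intensity
#' over its whole-cell disk footprint on the other channels.  The observed
#' image is the true image mixed through the spillover matrix, with optional
#' Poisson shot noise and uniformly placed hot pixels.
#'
#' @param layout a [generate_layout()] result.
#' @param panel a [imc_panel()].
#' @param profiles phenotype x channel intensity matrix
#'   (see [default_profiles()]).
#' @param spillover a [spillover_matrix()]; identity when `NULL`.
#' @param nucleus_radius,cell_radius disk radii in pixels.
#' @param nucleus_intensity mean nucleus-channel ion count per nucleus pixel.
#' @param noise list: `poisson` (logical), `hot_pixel_rate` (per pixel per
#'   channel), `hot_pixel_value`.
#' @param roi_id,pixel_size ROI identifier and microns per pixel.
#' @param seed RNG seed for the noise draws.
#' @return A `tme_roi`: list with `pixels` (H x W x C array), `panel`,
#'   `roi_id`, `site`, `pixel_size`, and the noise-free `truth` array.
#' @export
render_roi <- function(layout, panel, profiles = default_profiles(panel),
                       spillover = NULL, nucleus_radius = 4, cell_radius = 7,
                       nucleus_intensity = 20,
                       noise = list(poisson = FALSE, hot_pixel_rate = 0,
                                    hot_pixel_value = 200),
                       roi_id = "roi1", pixel_size = 1, seed = 1L) {
  gt <- layout$ground_truth
  W <- gt$width; H <- gt$height; C <- nrow(panel)
  if (is.null(spillover)) spillover <- spillover_matrix(C)
  if (nrow(spillover) != C)
    stopf("spillover dimension (%d) does not match panel size (%d)",
          nrow(spillover), C)
  miss <- setdiff(unique(layout$cells$phenotype), rownames(profiles))
  if (length(miss))
    stopf("no intensity profile for phenotype(s): %s", paste(miss, collapse = ", "))

  truth <- array(0, dim = c(H, W, C),
                 dimnames = list(NULL, NULL, panel$marker))
  nuc <- nucleus_channel(panel)
  for (r in seq_len(nrow(layout$cells))) {
    cx <- layout$cells$x[r]; cy <- layout$cells$y[r]
    ph <- layout$cells$phenotype[r]
    px <- rasterize_disk(cx, cy, nucleus_radius, W, H)
    truth[cbind(px, nuc)] <- truth[cbind(px, nuc)] + nucleus_intensity
    foot <- rasterize_disk(cx, cy, cell_radius, W, H)
    for (ch in seq_len(C)[-nuc]) {
      v <- profiles[ph, ch]
      if (v > 0) truth[cbind(foot, ch)] <- truth[cbind(foot, ch)] + v
    }
  }

  # observed_j = sum_i true_i * S[i, j]  per pixel
  flat <- matrix(truth, ncol = C)
  obs <- flat %*% unclass(spillover)
  set.seed(seed)
  if (isTRUE(noise$poisson)) obs[] <- stats::rpois(length(obs), lambda = obs)
  if (!is.null(noise$hot_pixel_rate) && noise$hot_pixel_rate > 0) {
    n_hot <- stats::rbinom(1, length(obs), noise$hot_pixel_rate)
    if (n_hot > 0)
      obs[sample.int(length(obs), n_hot)] <- noise$hot_pixel_value
  }
  pixels <- array(obs, dim = dim(truth), dimnames = dimnames(truth))

  structure(list(pixels = pixels, truth = truth, panel = panel,
                 roi_id = roi_id, site = gt$site, pixel_size = pixel_size,
                 layout = layout, spillover = spillover, seed = seed),
            class = "tme_roi")
}

#' @export
print.tme_roi <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<tme_roi> %s (site %s): %d x %d px, %d channels, %.2g um/px\n",
              x$roi_id, x$site, d[2], d[1], d[3], x$pixel_size))
  invisible(x)
}

#' @export
plot.tme_roi <- function(x, channel = 1, ...) {
  m <- x$pixels[, , channel]
  graphics::image(t(m)[, nrow(m):1], col = grDevices::hcl.colors(64, "inferno"),
                  axes = FALSE, main = dimnames(x$pixels)[[3]][channel], ...)
  invisible(x)
}

#' Generate a synthetic gene-by-cell count matrix
#'
#' Counts are negative-binomial per gene per cell with phenotype-specific
#' means: each phenotype's marker genes are elevated (`marker_mean`) over the
#' baseline (`base_mean`).  Mitochondrial genes (named with `mito_prefix`)
#' receive a share of each cell's signal so mitochondrial fractions are
#' realistic; a configurable fraction of barcodes are doublets formed by
#' summing two random parent cells, flagged in the ground truth.
#'
#' @param n_cells number of barcodes.
#' @param phenotypes either a character vector of per-cell phenotypes or a
#'   named composition to draw from.
#' @param n_genes total genes, including `n_mito` mitochondrial genes.
#' @param markers_per_phenotype marker genes per phenotype.
#' @param marker_mean,base_mean NB mean for marker genes, and the median NB
#'   mean of background genes.
#' @param base_sdlog log-normal spread (sdlog) of background gene means
#'   around `base_mean`, emulating the broad baseline expression spectrum of
#'   real count data (set 0 for a flat baseline).
#' @param dispersion NB size parameter (variance = mu + mu^2/size).
#' @param n_mito,mito_mean,mito_prefix mitochondrial gene block.
#' @param doublet_rate fraction of barcodes replaced by parent-cell sums.
#' @param site site label(s), recycled over cells.
#' @param seed RNG seed.
#' @return A list of class `tme_counts`: sparse `counts` (genes x cells),
#'   `meta` (per-cell site, phenotype, QC metrics, doublet flag),
#'   `ground_truth` (marker gene map, seed, doublet flags).
#' @export
generate_counts <- function(n_cells, phenotypes, n_genes = 2500,
                            markers_per_phenotype = 10, marker_mean = 50,
                            base_mean = 1, base_sdlog = 1, dispersion = 2,
                            n_mito = 10, mito_mean = 5, mito_prefix = "MT-",
                            doublet_rate = 0, site = "site1", seed = 1L) {
  if (dispersion <= 0) stopf("dispersion must be > 0")
  if (doublet_rate < 0 || doublet_rate >= 1) stopf("doublet_rate must be in [0, 1)")
  if (marker_mean < 0 || base_mean < 0 || mito_mean < 0) stopf("NB means must be >= 0")
  set.seed(seed)
  if (!is.null(names(phenotypes)) && is.numeric(phenotypes)) {
    phen <- sample(names(phenotypes), n_cells, replace = TRUE, prob = phenotypes)
  } else {
    phen <- rep_len(as.character(phenotypes), n_cells)
  }
  types <- sort(unique(phen))
  n_reg <- n_genes - n_mito
  if (n_reg < length(types) * markers_per_phenotype)
    stopf("n_genes too small for %d phenotypes x %d markers", length(types),
          markers_per_phenotype)
  genes <- c(sprintf("G%04d", seq_len(n_reg)), paste0(mito_prefix, seq_len(n_mito)))
  marker_map <- lapply(seq_along(types), function(i)
    genes[(i - 1L) * markers_per_phenotype + seq_len(markers_per_phenotype)])
  names(marker_map) <- types

  # per-phenotype mean vector over genes; background means are spread
  # log-normally so the gene-level mean-variance trend is informative
  base <- stats::rlnorm(n_reg, meanlog = log(base_mean), sdlog = base_sdlog)
  mu <- matrix(rep(c(base, rep(mito_mean, n_mito)), length(types)),
               n_genes, length(types), dimnames = list(genes, types))
  for (t in types) mu[marker_map[[t]], t] <- marker_mean

  counts <- matrix(0L, n_genes, n_cells)
  for (t in types) {
    idx <- which(phen == t)
    if (!length(idx)) next
    counts[, idx] <- stats::rnbinom(n_genes * length(idx), size = dispersion,
                                    mu = rep(mu[, t], times = length(idx)))
  }

  doublet <- rep(FALSE, n_cells)
  n_doub <- round(doublet_rate * n_cells)
  if (n_doub > 0) {
    which_doub <- sample.int(n_cells, n_doub)
    for (d in which_doub) {
      parents <- sample(setdiff(seq_len(n_cells), d), 2L)
      counts[, d] <- counts[, parents[1]] + counts[, parents[2]]
      phen[d] <- paste(sort(phen[parents]), collapse = "+")
    }
    doublet[which_doub] <- TRUE
  }

  rownames(counts) <- genes
  colnames(counts) <- sprintf("cell%05d", seq_len(n_cells))
  make_counts(Matrix::Matrix(counts, sparse = TRUE),
              site = rep_len(site, n_cells), phenotype = phen,
              doublet = doublet, mito_prefix = mito_prefix,
              ground_truth = list(marker_genes = marker_map, seed = seed,
                                  doublet = doublet, phenotype = phen))
}

#' Assemble a count-matrix container with QC metadata
#'
#' Computes per-cell total UMIs, genes detected and mitochondrial fraction
#' from the matrix, identifying mitochondrial genes by name prefix.
#'
#' @param counts genes x cells matrix (coerced to sparse).
#' @param site,patient per-cell labels (recycled).
#' @param phenotype,doublet optional per-cell annotations.
#' @param mito_prefix gene-name prefix marking mitochondrial genes.
#' @param ground_truth optional list carried through.
#' @return A list of class `tme_counts` with `counts`, `meta`, `mito_prefix`.
#' @export
make_counts <- function(counts, site = "site1", patient = "p1",
                        phenotype = NULL, doublet = NULL,
                        mito_prefix = "MT-", ground_truth = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (any(counts < 0)) stopf("counts must be non-negative")
  n <- ncol(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("G%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%05d", seq_len(n))
  mito <- startsWith(rownames(counts), mito_prefix)
  tot <- Matrix::colSums(counts)
  meta <- data.frame(
    barcode = colnames(counts),
    site = rep_len(site, n), patient = rep_len(patient, n),
    total_umi = tot,
    genes_detected = Matrix::colSums(counts > 0),
    mito_fraction = ifelse(tot > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / tot, 0),
    stringsAsFactors = FALSE)
  if (!is.null(phenotype)) meta$phenotype <- phenotype
  if (!is.null(doublet)) meta$doublet <- doublet
  structure(list(counts = counts, meta = meta, mito_prefix = mito_prefix,
                 ground_truth = ground_truth),
            class = "tme_counts")
}

#' @export
print.tme_counts <- function(x, ...) {
  cat(sprintf("<tme_counts> %d genes x %d cells; sites: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$meta$site), collapse = ", ")))
  invisible(x)
}

#' @export
dim.tme_counts <- function(x) dim(x$counts)
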