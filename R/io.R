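# File-format plumbing: multi-page TIFF ROIs with JSON sidecars, 16-bit mask
# TIFFs, MTX count matrices with gene/barcode TSVs, CSV tables, and
# ground-truth JSON round-trips.

#' Write an ROI to multi-page TIFF plus JSON sidecar
#'
#' One 32-bit float page per channel; the sidecar records the panel, site,
#' seed, pixel size and spillover matrix.
#'
#' @param roi a `tme_roi`.
#' @param path output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_roi <- function(roi, path) {
  scale <- max(roi$pixels, 1)
  pages <- lapply(seq_len(dim(roi$pixels)[3]), function(ch) {
    m <- roi$pixels[, , ch] / scale
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- list(roi_id = roi$roi_id, site = roi$site,
                  pixel_size = roi$pixel_size, seed = roi$seed,
                  intensity_scale = scale,
                  panel = list(marker = roi$panel$marker, role = roi$panel$role),
                  spillover = unclass(roi$spillover))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ROI written by [write_roi()]
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return A `tme_roi` (without the synthetic truth component).
#' @export
read_roi <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  panel <- imc_panel(side$panel$marker, side$panel$role)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  px <- array(0, dim = c(H, W, length(pages)),
              dimnames = list(NULL, NULL, panel$marker))
  scale <- side$intensity_scale %||% 1
  for (ch in seq_along(pages)) px[, , ch] <- pages[[ch]] * scale
  structure(list(pixels = px, panel = panel, roi_id = side$roi_id,
                 site = side$site, pixel_size = side$pixel_size,
                 spillover = spillover_matrix(mat = side$spillover),
                 seed = side$seed),
            class = "tme_roi")
}

#' Write a segmentation mask as 16-bit single-page TIFF
#' @param mask a `tme_mask`.
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535L) stopf("more than 65535 labels")
  m <- unclass(mask) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a mask written by [write_mask()]
#' @param path TIFF path.
#' @return integer label matrix of class `tme_mask`.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  lab <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  structure(lab, class = "tme_mask")
}

#' Write a layout (cells CSV + ground-truth JSON)
#' @param layout a `tme_layout`.
#' @param prefix path prefix; writes `<prefix>_cells.csv` and
#'   `<prefix>_truth.json`.
#' @export
write_layout <- function(layout, prefix) {
  utils::write.csv(layout$cells, paste0(prefix, "_cells.csv"), row.names = FALSE)
  jsonlite::write_json(layout$ground_truth, paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a layout written by [write_layout()]
#' @param prefix path prefix used at write time.
#' @return A `tme_layout`.
#' @export
read_layout <- function(prefix) {
  cells <- utils::read.csv(paste0(prefix, "_cells.csv"), stringsAsFactors = FALSE)
  gt <- jsonlite::read_json(paste0(prefix, "_truth.json"), simplifyVector = TRUE)
  gt$centroid <- cbind(x = cells$x, y = cells$y)
  gt$aggregates <- if (is.null(gt$aggregates)) list() else
    lapply(seq_len(nrow_safe(gt$aggregates)), function(i) as_agg(gt$aggregates, i))
  structure(list(cells = cells, ground_truth = gt), class = "tme_layout")
}

nrow_safe <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
as_agg <- function(a, i) {
  if (is.data.frame(a)) {
    list(center = unlist(a$center[i]), radius = a$radius[i], n = a$n[i],
         phenotype = unlist(a$phenotype[i]))
  } else a[[i]]
}

#' Write counts as MatrixMarket MTX with gene/barcode TSVs
#' @param x a `tme_counts`.
#' @param dir output directory; writes `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `meta.csv`.
#' @export
write_counts <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(gene = rownames(x$counts)),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(barcode = colnames(x$counts)),
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.csv(x$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read counts written by [write_counts()]
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and optionally `meta.csv`.
#' @param mito_prefix mitochondrial gene-name prefix.
#' @return A `tme_counts`.
#' @export
read_counts <- function(dir, mito_prefix = "MT-") {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.table(file.path(dir, "genes.tsv"), sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  bc <- utils::read.table(file.path(dir, "barcodes.tsv"), sep = "\t",
                          stringsAsFactors = FALSE)[[1]]
  dimnames(m) <- list(genes, bc)
  meta_path <- file.path(dir, "meta.csv")
  site <- "site1"; patient <- "p1"; phen <- NULL; doub <- NULL
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    site <- meta$site; patient <- meta$patient
    phen <- meta$phenotype; doub <- meta$doublet
  }
  make_counts(m, site = site, patient = patient, phenotype = phen,
              doublet = doub, mito_prefix = mito_prefix)
}

#' Write a cell table to CSV
#' @param cells a `tme_cells` table.
#' @param path output CSV.
#' @export
write_cells <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}
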