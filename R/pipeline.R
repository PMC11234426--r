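# Orchestration: configuration container, end-to-end IMC and RNA runs on
# directories of inputs, fixture generation, and run manifests.

config_defaults <- function() list(
  # transcriptomic arm
  min_genes = 500, max_genes = 5000, min_umi = 400, max_umi = 25000,
  max_mito = 0.15, min_cells_per_gene = 3, hvg = 2000, pcs = 20,
  resolution = 1.2, rna_k = 20, scale_factor = 1e4,
  min_pct = 0.25, logfc_threshold = 0.25, drop_doublets = TRUE,
  # IMC arm
  phenograph_k = 100, norm_pct = 99, artifact_distance = 15,
  nucleus_threshold = 5, cell_radius = 7, hot_pixel_threshold = 50,
  contrast_lower = 0, contrast_upper = 99,
  # spatial arm
  cn_k = 20, cn_clusters = 15, n_perm = 1000, interaction_alpha = 0.01,
  patch_eps = 20, patch_min_size = 20,
  # run
  seed = 1L)

#' Pipeline configuration
#'
#' Every tunable threshold of the pipeline with its default: QC windows
#' (`min_genes` 500, `max_genes` 5000, `min_umi` 400, `max_umi` 25000,
#' `max_mito` 0.15, `min_cells_per_gene` 3), `hvg` 2000, `pcs` 20,
#' `resolution` 1.2, `phenograph_k` 100, `norm_pct` 99, `artifact_distance`
#' 15 px, CN window `cn_k` 20, `cn_clusters` 15, and the seed.  Unknown keys
#' are rejected.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `tme_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "tme_config")
}

#' Write / read a configuration as JSON
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

write_manifest <- function(dir, config, extra = list()) {
  cfg_path <- file.path(dir, "config.json")
  write_config(config, cfg_path)
  manifest <- c(list(config_hash = unname(tools::md5sum(cfg_path)),
                     seed = config$seed,
                     package_version = as.character(utils::packageVersion("spatialTME"))),
                extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the IMC arm end to end
#'
#' For every `*.tiff` ROI under `input_dir` (with JSON sidecars):
#' compensation -> hot-pixel removal -> contrast -> segmentation ->
#' quantification, then pooled Phenograph-style clustering, Ro/e by site,
#' CN composition/k-means, permutation interaction tests and TLS-like patch
#' detection.  All tables are written as CSV with a run manifest.
#'
#' @param config a [pipeline_config()].
#' @param input_dir directory of `write_roi()` outputs.
#' @param output_dir destination directory (created).
#' @param target_phenotypes patch target set passed to [detect_patches()];
#'   when `NULL`, clusters whose top mean marker is among `target_markers`
#'   are used.
#' @param target_markers markers identifying the TLS compartment clusters
#'   (default CD20/CD4, the B and helper-T lineage channels).
#' @return `output_dir`, invisibly; partial outputs are retained on error.
#' @export
run_imc <- function(config, input_dir, output_dir,
                    target_phenotypes = NULL,
                    target_markers = c("CD20", "CD4")) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list.files(input_dir, pattern = "\\.tiff?$", full.names = TRUE)
  if (!length(paths)) stopf("stage input: no TIFF ROIs in %s", input_dir)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  tables <- list()
  for (p in paths) {
    roi <- stage("read", read_roi(p))
    roi <- stage("compensate", compensate_spillover(roi, roi$spillover))
    roi <- stage("denoise", remove_hot_pixels(roi, config$hot_pixel_threshold))
    roi <- stage("contrast", enhance_contrast(roi, config$contrast_lower,
                                              config$contrast_upper))
    if (!any(roi$panel$role == "nucleus"))
      stopf("stage 'segment' failed: panel of %s has no nucleus channel", roi$roi_id)
    # contrast rescales to [0,1]; threshold follows suit
    mask <- stage("segment",
                  segment_cells(roi, nucleus_threshold = 0.1,
                                distance_limit = config$artifact_distance,
                                cell_radius = config$cell_radius))
    cells <- stage("quantify", quantify_cells(roi, mask, config$norm_pct))
    write_mask(mask, file.path(output_dir, paste0(roi$roi_id, "_mask.tiff")))
    tables[[length(tables) + 1L]] <- cells
  }
  cells <- do.call(rbind, lapply(tables, as.data.frame))
  cells$cell_id <- seq_len(nrow(cells))
  attr(cells, "markers") <- attr(tables[[1]], "markers")
  attr(cells, "pixel_size") <- attr(tables[[1]], "pixel_size")
  attr(cells, "roi_dims") <- attr(tables[[1]], "roi_dims")
  class(cells) <- c("tme_cells", "data.frame")

  cl <- stage("cluster", cluster_graph(marker_matrix(cells),
                                       k_neighbors = min(config$phenograph_k,
                                                         nrow(cells) - 1L),
                                       resolution = 1, seed = config$seed))
  cells$phenotype <- paste0("C", cl$cluster)
  ro <- stage("roe", roe(table(cells$phenotype, cells$site)))
  graph <- stage("graph", build_graph(cells, "knn", k = config$cn_k))
  comp <- stage("cn", cn_compose(cells, graph))
  k_cn <- min(config$cn_clusters, nrow(unique(comp)))
  cn <- stage("cn", cn_cluster(comp, k_cn = k_cn, seed = config$seed))
  cells$cn_id <- cn$cn
  inter <- stage("interaction",
                 interaction_test(cells, graph, n_perm = config$n_perm,
                                  alpha = config$interaction_alpha,
                                  seed = config$seed))
  if (is.null(target_phenotypes)) {
    mm <- cl$means
    dominant <- colnames(mm)[apply(mm, 1L, which.max)]
    hit <- which(dominant %in% intersect(target_markers, colnames(mm)))
    target_phenotypes <- if (length(hit)) paste0("C", hit)
                         else unique(cells$phenotype)[1]
  }
  patches <- stage("patches",
                   detect_patches(cells, target_phenotypes,
                                  eps = config$patch_eps,
                                  min_size = config$patch_min_size))

  write_cells(cells, file.path(output_dir, "cells.csv"))
  utils::write.csv(as.data.frame(ro$roe), file.path(output_dir, "roe.csv"))
  utils::write.csv(graph_edges(graph), file.path(output_dir, "graph_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(inter), file.path(output_dir, "interactions.csv"),
                   row.names = FALSE)
  utils::write.csv(patches$patches, file.path(output_dir, "patches.csv"),
                   row.names = FALSE)
  write_manifest(output_dir, config,
                 list(n_cells = nrow(cells), n_rois = length(paths),
                      n_clusters = max(cl$cluster), n_patches = nrow(patches$patches)))
  invisible(output_dir)
}

#' Run the transcriptomic arm end to end
#'
#' qc -> log-normalize -> HVG -> PCA -> graph clustering -> marker ranking
#' -> annotation -> Ro/e by site -> signature scores, with CSV outputs and
#' a manifest.  An empty post-QC matrix stops gracefully with a warning.
#'
#' @param config a [pipeline_config()].
#' @param input_dir a [write_counts()] directory.
#' @param output_dir destination directory (created).
#' @param marker_map optional label -> markers list for annotation.
#' @param signatures optional named list of signature gene vectors scored
#'   with `mean_z` (default: the TRM signature, scored when any member is
#'   present).
#' @return `output_dir` invisibly, or `NULL` when QC empties the matrix.
#' @export
run_rna <- function(config, input_dir, output_dir, marker_map = NULL,
                    signatures = list(TRM = trm_signature())) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  x <- stage("read", read_counts(input_dir))
  x <- stage("qc", qc_filter(x, config$min_genes, config$max_genes,
                             config$min_umi, config$max_umi, config$max_mito,
                             config$min_cells_per_gene,
                             drop_doublets = config$drop_doublets))
  if (ncol(x$counts) == 0L) {
    warnf("no cell passed QC; stopping after the qc stage")
    write_manifest(output_dir, config, list(n_cells = 0L))
    return(invisible(NULL))
  }
  norm <- stage("lognormalize", lognormalize(x, config$scale_factor))
  hvg <- stage("hvg", select_hvg(x$counts, n = min(config$hvg, nrow(norm))))
  emb <- stage("pca", embed_pca(norm, hvg, n_pcs = config$pcs))
  cl <- stage("cluster", cluster_graph(emb, k_neighbors = config$rna_k,
                                       resolution = config$resolution,
                                       seed = config$seed))
  markers <- stage("markers", rank_markers(norm, cl, config$min_pct,
                                           config$logfc_threshold))
  ann <- if (!is.null(marker_map))
    stage("annotate", annotate_clusters(norm, cl, marker_map)) else NULL
  ro <- stage("roe", roe(table(cl$cluster, x$meta$site)))
  sig <- lapply(signatures, function(g) {
    if (any(g %in% rownames(norm))) score_signature(norm, g, "mean_z") else NULL
  })

  out_meta <- cbind(x$meta, cluster = cl$cluster)
  if (!is.null(ann)) out_meta$label <- ann$label[match(cl$cluster, ann$cluster)]
  for (nm in names(sig)) if (!is.null(sig[[nm]])) out_meta[[paste0("score_", nm)]] <- sig[[nm]]
  utils::write.csv(out_meta, file.path(output_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(markers, file.path(output_dir, "markers.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ro$roe), file.path(output_dir, "roe.csv"))
  if (!is.null(ann))
    utils::write.csv(ann, file.path(output_dir, "annotation.csv"), row.names = FALSE)
  write_manifest(output_dir, config,
                 list(n_cells = ncol(x$counts), n_genes = nrow(x$counts),
                      n_clusters = max(cl$cluster)))
  invisible(output_dir)
}

#' Generate the synthetic fixture set
#'
#' Emits a small or medium synthetic dataset (ROIs, layouts, counts) with
#' planted site-specific composition (plasma/B enrichment in the adrenal
#' site), TLS-like aggregates in the immunogenic sites, and a 5-phenotype
#' count matrix, as used by the test suite.
#'
#' @param dir destination directory.
#' @param seed RNG seed.
#' @param scale `"small"` (default; <= 2000 cells) or `"medium"`.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1L, scale = c("small", "medium")) {
  scale <- match.arg(scale)
  dir.create(file.path(dir, "rois"), recursive = TRUE, showWarnings = FALSE)
  n_per_site <- if (scale == "small") 150L else 600L
  panel <- imc_panel(
    c("DNA1", "CD20", "CD4", "CD8", "PanCK", "CD68", "CD38", "CollagenI"),
    c("nucleus", rep("lineage", 6), "structure"))
  comp <- site_compositions()
  sites <- colnames(comp)
  # phenotype order matches the lineage channel order: B -> CD20,
  # CD4 T memory -> CD4, CD8 T -> CD8, Epithelial -> PanCK,
  # Macrophage -> CD68, Plasma -> CD38
  profiles <- default_profiles(panel, phenotypes = rownames(comp))
  for (i in seq_along(sites)) {
    s <- sites[i]
    aggs <- if (s %in% c("adrenal", "lung"))
      list(list(center = c(120, 120), radius = 30, n = 50,
                phenotype = c(B = 0.6, `CD4 T memory` = 0.4)))
    else list()
    lay <- generate_layout(n_per_site, comp[, s], width = 400, height = 400,
                           aggregates = aggs, site = s, seed = seed + i)
    roi <- render_roi(lay, panel, profiles,
                      spillover = random_spillover(nrow(panel), 0.05),
                      noise = list(poisson = TRUE, hot_pixel_rate = 1e-4,
                                   hot_pixel_value = 200),
                      roi_id = paste0("roi_", s), seed = seed + i)
    write_roi(roi, file.path(dir, "rois", paste0("roi_", s, ".tiff")))
    write_layout(lay, file.path(dir, "rois", paste0("roi_", s)))
  }
  counts <- generate_counts(
    n_cells = if (scale == "small") 1000L else 4000L,
    phenotypes = c(B = 0.2, `CD4 T memory` = 0.2, `CD8 T` = 0.2,
                   Epithelial = 0.2, Macrophage = 0.2),
    seed = seed)
  write_counts(counts, file.path(dir, "counts"))
  jsonlite::write_json(list(seed = seed, scale = scale),
                       file.path(dir, "fixtures.json"), auto_unbox = TRUE)
  invisible(dir)
}

# Site-specific phenotype composition emulating the organ-specific TME:
# B/plasma enrichment in the adrenal site, immune-poor liver, epithelial-
# dominated brain.
site_compositions <- function() {
  phen <- c("B", "CD4 T memory", "CD8 T", "Epithelial", "Macrophage", "Plasma")
  m <- cbind(
    lung    = c(0.15, 0.15, 0.12, 0.30, 0.18, 0.10),
    brain   = c(0.03, 0.07, 0.08, 0.55, 0.22, 0.05),
    liver   = c(0.03, 0.06, 0.08, 0.50, 0.28, 0.05),
    adrenal = c(0.22, 0.18, 0.10, 0.20, 0.10, 0.20))
  rownames(m) <- phen
  m
}
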