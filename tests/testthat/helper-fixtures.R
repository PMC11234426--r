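# multi-site spatial fixture shared by the CN acceptance check
site_compositions_fixture <- function(seed) {
  comps <- list(
    lung    = c(B = 0.15, `CD4 T memory` = 0.15, `CD8 T` = 0.12,
                Epithelial = 0.30, Macrophage = 0.18, Plasma = 0.10),
    brain   = c(B = 0.03, `CD4 T memory` = 0.07, `CD8 T` = 0.08,
                Epithelial = 0.55, Macrophage = 0.22, Plasma = 0.05),
    liver   = c(B = 0.03, `CD4 T memory` = 0.06, `CD8 T` = 0.08,
                Epithelial = 0.50, Macrophage = 0.28, Plasma = 0.05),
    adrenal = c(B = 0.22, `CD4 T memory` = 0.18, `CD8 T` = 0.10,
                Epithelial = 0.20, Macrophage = 0.10, Plasma = 0.20))
  cells <- do.call(rbind, lapply(seq_along(comps), function(i) {
    s <- names(comps)[i]
    aggs <- if (s %in% c("lung", "adrenal"))
      list(list(center = c(150, 150), radius = 35, n = 60,
                phenotype = c(B = 0.6, `CD4 T memory` = 0.4)))
    else list()
    lay <- generate_layout(400, comps[[i]], width = 600, height = 600,
                           min_sep = 5, aggregates = aggs, site = s,
                           seed = seed + i)
    cbind(lay$cells, roi_id = paste0("roi_", s))
  }))
  cells$cell_id <- seq_len(nrow(cells))
  list(cells = cells)
}
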