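cells_df <- function(x, y, phenotype, roi = "r1") {
  data.frame(cell_id = seq_along(x), x = x, y = y,
             phenotype = phenotype, roi_id = roi, stringsAsFactors = FALSE)
}

checkerboard <- function(n_side = 15) {
  g <- expand.grid(x = 0:(n_side - 1), y = 0:(n_side - 1))
  cells_df(g$x, g$y, ifelse((g$x + g$y) %% 2 == 0, "A", "B"))
}

test_that("build_graph: exact kNN per image, ties by id, no cross-image edges", {
  # 3 collinear cells at x = 0, 1, 3 with k = 1
  c3 <- cells_df(c(0, 1, 3), c(0, 0, 0), c("A", "A", "A"))
  g1 <- build_graph(c3, "knn", k = 1)
  expect_identical(g1$neighbors, list(2L, 1L, 2L))

  # k = n - 1: complete directed graph
  gc <- build_graph(c3, "knn", k = 2)
  expect_identical(lapply(gc$neighbors, sort), list(2:3, c(1L, 3L), 1:2))

  # k >= n capped with warning
  expect_warning(gk <- build_graph(c3, "knn", k = 5), "capped")
  expect_identical(lengths(gk$neighbors), rep(2L, 3))

  # two concatenated images share no edges
  two <- rbind(cells_df(c(0, 1), c(0, 0), c("A", "B"), "im1"),
               cells_df(c(0.1, 1.1), c(0, 0), c("A", "B"), "im2"))
  two$cell_id <- 1:4
  g2 <- build_graph(two, "knn", k = 1)
  expect_identical(g2$neighbors, list(2L, 1L, 4L, 3L))

  # radius mode
  gr <- build_graph(c3, "radius", r = 1.5)
  expect_identical(gr$neighbors, list(2L, 1L, integer(0)))
  expect_error(build_graph(c3, "radius"), "r > 0")
  expect_error(build_graph(cells_df(0, 0, "A")), ">= 2")

  # edge list export round-trips the neighbor structure
  e <- graph_edges(g1)
  expect_identical(e$to[e$from == 3], 2L)
})

test_that("cn_compose windows include the center and sum to 1", {
  # homogeneous image: one-hot rows
  set.seed(31)
  hom <- cells_df(runif(30, 0, 100), runif(30, 0, 100), "A")
  gh <- build_graph(hom, k = 5)
  ch <- cn_compose(hom, gh, categories = c("A", "B"))
  expect_true(all(ch[, "A"] == 1) && all(ch[, "B"] == 0))

  # a B cell with 10 B and 10 T among its 20 neighbors: (11/21, 10/21)
  center <- cells_df(0, 0, "B")
  ring <- data.frame(cell_id = 2:21,
                     x = 3 * cos(2 * pi * (1:20) / 20),
                     y = 3 * sin(2 * pi * (1:20) / 20),
                     phenotype = rep(c("B", "T"), 10), roi_id = "r1")
  far <- cells_df(50, 50, "T"); far$cell_id <- 22
  cells <- rbind(center, ring, far)
  g <- build_graph(cells, k = 20)
  comp <- cn_compose(cells, g)
  expect_equal(unname(comp[1, c("B", "T")]), c(11 / 21, 10 / 21))
  expect_equal(unname(rowSums(comp)), rep(1, nrow(cells)))

  # neighbors-only window flag
  comp0 <- cn_compose(cells, g, include_center = FALSE)
  expect_equal(unname(comp0[1, c("B", "T")]), c(10 / 20, 10 / 20))

  expect_error(cn_compose(cells, g, categories = c("B")), "unknown category")
})

test_that("cn_cluster recovers planted niches and obeys simplex geometry", {
  # two spatially separated homogeneous blocks
  set.seed(32)
  blk <- rbind(cells_df(runif(100, 0, 80), runif(100, 0, 80), "A"),
               cells_df(runif(100, 300, 380), runif(100, 300, 380), "B"))
  blk$cell_id <- 1:200
  g <- build_graph(blk, k = 10)
  comp <- cn_compose(blk, g)
  cn <- cn_cluster(comp, k_cn = 2, seed = 7)
  expect_equal(adjusted_rand_index(cn$cn, rep(1:2, each = 100)), 1)
  expect_equal(unname(rowSums(cn$centroids)), rep(1, 2), tolerance = 1e-9)

  # k_cn = 1: centroid is the global mean composition
  cn1 <- cn_cluster(comp, k_cn = 1, seed = 7)
  expect_equal(unname(cn1$centroids[1, ]), unname(colMeans(comp)))

  # duplicating every row leaves centroids unchanged
  cn2 <- cn_cluster(rbind(comp, comp), k_cn = 2, seed = 7)
  expect_equal(sort(cn2$centroids[, "A"]), sort(cn$centroids[, "A"]),
               tolerance = 1e-9)

  expect_error(cn_cluster(comp[c(1, 1, 1), ], k_cn = 2), "distinct")
})

test_that("interaction_test: degenerate single phenotype and planted lattice", {
  # single phenotype: observed = mean degree, permutation-invariant, p = 1
  set.seed(33)
  one <- cells_df(runif(40, 0, 100), runif(40, 0, 100), "A")
  go <- build_graph(one, k = 5)
  it1 <- interaction_test(one, go, n_perm = 100, seed = 1)
  expect_equal(it1$observed, 5)
  expect_equal(it1$p_interact, 1)
  expect_equal(it1$p_avoid, 1)
  expect_identical(it1$classification, "none")

  # alternating lattice: opposite types attract, like types avoid
  cb <- checkerboard(15)
  gcb <- build_graph(cb, k = 4)
  it <- interaction_test(cb, gcb, n_perm = 500, alpha = 0.01, seed = 2)
  get <- function(f, t, col) it[it$from == f & it$to == t, col]
  expect_identical(get("A", "B", "classification"), "interaction")
  expect_identical(get("B", "A", "classification"), "interaction")
  expect_identical(get("A", "A", "classification"), "avoidance")
  expect_identical(get("B", "B", "classification"), "avoidance")
  # interior observed statistic is 4 (all four lattice neighbors opposite);
  # border cells pull the mean slightly below 4 but it stays near 4
  expect_gt(get("A", "B", "observed"), 3.5)
  # p-values live in (0, 1] with the add-one estimator
  expect_true(all(it$p_interact > 0 & it$p_interact <= 1))

  expect_error(interaction_test(cb, gcb, n_perm = 50), "n_perm")
})

test_that("interaction statistic equals the brute-force all-pairs scan", {
  set.seed(34)
  for (i in 1:3) {
    n <- sample(50:200, 1)
    cells <- cells_df(runif(n, 0, 300), runif(n, 0, 300),
                      sample(c("A", "B", "C"), n, replace = TRUE))
    g <- build_graph(cells, k = 10)
    it <- interaction_test(cells, g, n_perm = 100, seed = 3)
    bf <- spatialTME:::interaction_stat_bruteforce(cells, 10)
    for (a in rownames(bf)) for (b in colnames(bf)) {
      got <- it$observed[it$from == a & it$to == b]
      expect_equal(got, unname(bf[a, b]))
    }
  }
})

test_that("pairs absent from an image are recorded, not dropped", {
  both <- rbind(cells_df(c(0, 1, 2, 5, 6, 7), c(0, 0, 0, 1, 1, 1),
                         rep(c("A", "B"), each = 3), "im1"),
                cells_df(c(0, 1, 2, 5, 6, 7), c(0, 0, 0, 1, 1, 1),
                         "A", "im2"))
  both$cell_id <- 1:12
  g <- build_graph(both, k = 2)
  it <- interaction_test(both, g, n_perm = 100, seed = 4)
  expect_identical(unique(it$classification[it$roi_id == "im2" &
                                            (it$from == "B" | it$to == "B")]),
                   "absent")
})

test_that("detect_patches finds planted aggregates and nothing else", {
  # no target cells: 0 patches, not an error
  set.seed(35)
  bg <- cells_df(runif(100, 0, 400), runif(100, 0, 400), "T")
  p0 <- detect_patches(bg, target_phenotypes = "B", eps = 20, min_size = 10)
  expect_equal(nrow(p0$patches), 0)
  expect_true(all(p0$membership == 0))

  # one planted 60-cell disk aggregate: exactly one patch with all members
  lay <- generate_layout(150, c(B = 0.05, T = 0.95), width = 500, height = 500,
                         aggregates = list(list(center = c(150, 150), radius = 30,
                                                n = 60, phenotype = "B")),
                         seed = 36)
  p1 <- detect_patches(lay$cells, "B", eps = 20, min_size = 10)
  expect_equal(nrow(p1$patches), 1)
  agg_rows <- which(lay$cells$aggregate == 1)
  expect_true(all(p1$membership[agg_rows] == 1))
  expect_gt(p1$patches$area_um2[1], 0)

  # two aggregates farther apart than 2 x radius + eps: exactly two patches
  lay2 <- generate_layout(0, c(B = 1),
                          aggregates = list(
                            list(center = c(100, 100), radius = 30, n = 50, phenotype = "B"),
                            list(center = c(300, 300), radius = 30, n = 50, phenotype = "B")),
                          width = 500, height = 500, seed = 37)
  p2 <- detect_patches(lay2$cells, "B", eps = 20, min_size = 10)
  expect_equal(nrow(p2$patches), 2)

  expect_error(detect_patches(bg, "B", eps = 0), "eps")
  expect_error(detect_patches(bg, "B", min_size = 0), "min_size")
})

test_that("patch detection is rigid-motion invariant", {
  lay <- generate_layout(100, c(B = 0.1, T = 0.9), width = 400, height = 400,
                         aggregates = list(list(center = c(120, 250), radius = 25,
                                                n = 40, phenotype = "B")),
                         seed = 38)
  p <- detect_patches(lay$cells, "B", eps = 20, min_size = 10)
  th <- pi / 5
  rot <- lay$cells
  rot$x <- cos(th) * lay$cells$x - sin(th) * lay$cells$y + 300
  rot$y <- sin(th) * lay$cells$x + cos(th) * lay$cells$y + 100
  pr <- detect_patches(rot, "B", eps = 20, min_size = 10)
  expect_equal(nrow(pr$patches), nrow(p$patches))
  expect_equal(sort(pr$patches$n_cells), sort(p$patches$n_cells))
  expect_equal(sort(pr$patches$area_um2), sort(p$patches$area_um2),
               tolerance = 1e-6)
})

test_that("patch_profile reports compositions and filtered marker means", {
  lay <- generate_layout(60, c(B = 0.05, T = 0.95), width = 400, height = 400,
                         aggregates = list(list(center = c(100, 100), radius = 25,
                                                n = 30, phenotype = c(B = 0.5, T = 0.5))),
                         seed = 39)
  cells <- lay$cells
  cells$TIM3 <- ifelse(cells$aggregate == 1 & cells$phenotype == "T", 0.9, 0.1)
  ps <- detect_patches(cells, c("B", "T"), eps = 15, min_size = 10)
  # background T cells are sparse (60 in 160000 um^2) relative to min_size
  expect_equal(nrow(ps$patches), 1)
  prof <- patch_profile(ps, cells, markers = "TIM3", phenotype_filter = "T")
  fr <- prof[, c("frac_B", "frac_T")]
  expect_equal(rowSums(fr), 1, ignore_attr = TRUE)
  # planted exhaustion marker on patch T cells
  in_patch_t <- ps$membership > 0 & cells$phenotype == "T"
  expect_equal(prof$mean_TIM3, mean(cells$TIM3[in_patch_t]))
  expect_gt(prof$mean_TIM3, 0.85)

  # pure-B patch is one-hot at B
  layb <- generate_layout(0, c(B = 1),
                          aggregates = list(list(center = c(50, 50), radius = 20,
                                                 n = 25, phenotype = "B")),
                          width = 200, height = 200, seed = 40)
  psb <- detect_patches(layb$cells, "B", eps = 15, min_size = 5)
  profb <- patch_profile(psb, layb$cells)
  expect_equal(profb$frac_B, 1)

  expect_error(patch_profile(ps, cells, markers = "CD999"), "absent")
})
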