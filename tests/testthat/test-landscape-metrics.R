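mask_in <- function(w, h, cells) {
  m <- matrix(FALSE, h, w)
  for (p in cells) m[p[2] + 1, p[1] + 1] <- TRUE
  m
}

test_that("patch geometry counts areas and rook perimeters", {
  m <- mask_in(5, 5, list(c(2, 2)))
  pg <- patch_geometry(m)
  expect_equal(pg$area_cells, 1L)
  expect_equal(pg$perimeter_edges, 4L)
  m <- mask_in(5, 5, list(c(1, 1), c(2, 1), c(1, 2), c(2, 2)))
  pg <- patch_geometry(m)
  expect_equal(pg$area_cells, 4L)
  expect_equal(pg$perimeter_edges, 8L)
})

test_that("patch geometry matches the brute-force edge count on random masks", {
  set.seed(89)
  for (i in 1:200) {
    m <- matrix(runif(225) < runif(1, 0.2, 0.8), 15, 15)
    for (conn in c(4, 8)) {
      pg <- patch_geometry(m, conn)
      want <- flood_fill_oracle(m, conn)
      per <- perimeter_oracle(m, want$labels, want$n)
      expect_equal(nrow(pg), want$n)
      expect_equal(sort(pg$perimeter_edges), sort(per))
      expect_equal(sort(pg$area_cells), sort(tabulate(want$labels[m], want$n)))
    }
  }
})

test_that("hand-computed metric examples are reproduced exactly", {
  g <- create_grid(10, 10, 50)
  # one m x m square patch: maximally compact, LSI exactly 1
  sq <- matrix(FALSE, 10, 10); sq[2:4, 2:4] <- TRUE
  expect_equal(compute_class_metrics(sq, g)$lsi, 1)
  # 1 x 4 strip: E = 10, min edge for 4 cells = 8
  strip <- mask_in(10, 10, list(c(2, 5), c(3, 5), c(4, 5), c(5, 5)))
  expect_equal(compute_class_metrics(strip, g)$lsi, 1.25, tolerance = 1e-9)
  # 2 x 2 patch in a 10 x 10 grid: cohesion = 100 (1 - 8/16) / (1 - 1/10)
  blk <- mask_in(10, 10, list(c(4, 4), c(5, 4), c(4, 5), c(5, 5)))
  expect_equal(compute_class_metrics(blk, g)$cohesion, 500 / 9, tolerance = 1e-9)
  # whole-grid patch: LPI = 100 and LSI = 1
  full <- matrix(TRUE, 10, 10)
  mfull <- compute_class_metrics(full, g)
  expect_equal(mfull$lpi, 100)
  expect_equal(mfull$lsi, 1)
  expect_equal(mfull$n_patches, 1L)
  expect_equal(mfull$mean_patch_area, 25)  # 100 cells x 0.25 ha
})

test_that("degenerate masks are flagged undefined, not zero", {
  g <- create_grid(6, 6, 50)
  m <- compute_class_metrics(matrix(FALSE, 6, 6), g)
  expect_equal(m$n_patches, 0L)
  expect_true(is.na(m$lsi) && is.na(m$lpi) && is.na(m$cohesion) &&
              is.na(m$mean_patch_area))
  g1 <- create_grid(1, 1, 50)
  m1 <- compute_class_metrics(matrix(TRUE, 1, 1), g1)
  expect_true(is.na(m1$cohesion))  # Z = 1
  expect_equal(m1$lpi, 100)
})

test_that("metric bounds hold on random masks", {
  g <- create_grid(15, 15, 50)
  set.seed(97)
  for (i in 1:500) {
    m <- matrix(runif(225) < runif(1, 0.05, 0.95), 15, 15)
    if (!any(m)) next
    cm <- compute_class_metrics(m, g, sample(c(4, 8), 1))
    expect_gte(cm$lsi, 1)
    expect_gt(cm$lpi, 0); expect_lte(cm$lpi, 100)
    expect_gte(cm$cohesion, 0); expect_lte(cm$cohesion, 100)
    expect_equal(cm$n_patches * cm$mean_patch_area, cm$class_cells * 0.25)
  }
})

test_that("bridging two patches merges them and grows the largest patch", {
  g <- create_grid(12, 12, 50)
  set.seed(101)
  for (i in 1:20) {
    m <- matrix(runif(144) < 0.35, 12, 12)
    before <- compute_class_metrics(m, g)
    if (before$n_patches < 2) next
    # add one cell adjacent to at least two patches if one exists
    lab <- label_patches(m, 8)$labels
    cand <- which(!m)
    bridge <- NULL
    for (idx in sample(cand)) {
      x <- (idx - 1) %/% 12; y <- (idx - 1) %% 12
      nb <- c()
      for (dx in -1:1) for (dy in -1:1) {
        nx <- x + dx; ny <- y + dy
        if (nx >= 0 && nx < 12 && ny >= 0 && ny < 12)
          nb <- c(nb, lab[nx * 12 + ny + 1])
      }
      if (length(unique(nb[nb > 0])) >= 2) { bridge <- idx; break }
    }
    if (is.null(bridge)) next
    m[bridge] <- TRUE
    after <- compute_class_metrics(m, g)
    expect_lte(after$n_patches, before$n_patches)
    expect_gte(after$lpi, before$lpi)
  }
})

test_that("the metrics table covers fields, habitat and crop classes", {
  res <- small_landscape(seed = 6, prop = 0.3,
                         crops = data.frame(name = c("a", "b"),
                                            fraction = c(0.5, 0.5),
                                            specialization = c(0, 0)))
  tab <- res$metrics
  expect_setequal(unique(tab$class), c("fields", "others", "crop1", "crop2"))
  # habitat class excludes road cells: class cells + fields + roads-on-others
  g <- res$grid
  others_cells <- tab$value[tab$class == "others" & tab$metric == "class.cells"]
  expect_equal(others_cells, sum(g$landcover == 0L & !g$road))
})
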