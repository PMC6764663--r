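test_that("supercover rasterization flags exactly the intersected cells", {
  g <- create_grid(4, 2, 50)
  m <- rasterize_roads(list(rbind(c(25, 25), c(175, 25))), g)
  hit <- which(m, arr.ind = TRUE)
  expect_equal(sum(m), 4L)
  expect_true(all(hit[, "row"] == 1L))  # y = 0 row
  expect_setequal(hit[, "col"], 1:4)
  expect_false(any(rasterize_roads(list(), g)))
})

test_that("corner-to-corner diagonals follow the closed-square rule", {
  g <- create_grid(3, 3, 50)
  seg <- list(rbind(c(50, 50), c(100, 100)))  # diagonal of the center cell
  m <- rasterize_roads(seg, g)
  expect_equal(m, supercover_oracle(seg, g))
  expect_true(m[2, 2])           # the traversed cell
  expect_true(m[1, 1] && m[3, 3])  # cells sharing the touched corners
})

test_that("random polylines match the brute-force intersection oracle", {
  g <- create_grid(10, 10, 50)
  set.seed(31)
  for (i in 1:5) {
    pls <- lapply(1:5, function(k)
      matrix(runif(6, 0, 500), ncol = 2))
    expect_equal(rasterize_roads(pls, g), supercover_oracle(pls, g))
    # additivity: union of per-line masks
    per_line <- lapply(pls, function(pl) rasterize_roads(list(pl), g))
    expect_equal(rasterize_roads(pls, g), Reduce(`|`, per_line))
  }
})

test_that("vector road files load, fit the extent, and rasterize", {
  g <- create_grid(20, 10, 50)
  path <- withr::local_tempfile(fileext = ".geojson")
  # one horizontal line across the map (in arbitrary source coordinates)
  writeLines(jsonlite::toJSON(list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = NULL, geometry = list(
      type = "LineString",
      coordinates = list(c(3, 7), c(13, 7), c(3, 6.999), c(3, 7.001)))))),
    auto_unbox = TRUE), path)
  rn <- load_road_vector(path, g)
  expect_s3_class(rn, "lgraf_roads")
  row_hits <- rowSums(rn$road_mask)
  expect_true(any(row_hits == 20))  # a full row flagged
  # degenerate bounding box rejected
  bad <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(type = "Feature", properties = NULL,
    geometry = list(type = "LineString",
                    coordinates = list(c(1, 1), c(1, 2)))), auto_unbox = TRUE),
    bad)
  expect_error(load_road_vector(bad, g), "degenerate")
  expect_error(load_road_vector(withr::local_tempfile(), g), "cannot read")
})

test_that("straight-road generation spans the grid and honors min distance", {
  g <- create_grid(20, 20, 50)
  set.seed(37)
  one <- generate_roads_graffe(g, 20, 5)
  expect_equal(one$total_road_cells, 20L)
  expect_length(one$polylines, 1L)
  expect_equal(generate_roads_graffe(g, 0, 0)$total_road_cells, 0L)
  for (s in 1:50) {
    set.seed(s)
    rn <- generate_roads_graffe(g, 150, 5)
    expect_gte(rn$total_road_cells, 1L)
    # offsets of same-orientation roads all >= 5 apart
    offs <- sapply(rn$polylines, function(pl)
      if (pl[1, 2] == pl[2, 2]) c("h", pl[1, 2]) else c("v", pl[1, 1]))
    for (orient in c("h", "v")) {
      o <- sort(as.numeric(offs[2, offs[1, ] == orient]))
      if (length(o) > 1) expect_true(all(diff(o) >= 5 * 50))
    }
    # total close to request: within one full-span road
    expect_gte(rn$total_road_cells, min(150L, rn$total_road_cells))
    expect_lte(rn$total_road_cells - 150L, 20L)
    # every road cell lies on the polyline-derived mask
    expect_equal(rn$road_mask, rasterize_roads(rn$polylines, g))
  }
})

test_that("noise-guided walker roads are deterministic and reach the target length", {
  g <- create_grid(30, 30, 50)
  set.seed(41); a <- generate_roads_perlin(g, 90, 3)
  set.seed(41); b <- generate_roads_perlin(g, 90, 3)
  expect_identical(a$polylines, b$polylines)
  expect_identical(a$road_mask, b$road_mask)
  for (s in 1:10) {
    set.seed(s)
    rn <- generate_roads_perlin(g, 90, 3)
    expect_gte(rn$total_road_cells, 90L)
    expect_lte(rn$total_road_cells, 90L + 4L * 60L)  # one walk at most
  }
})

test_that("a pure distance-weighted walker approaches its target monotonically", {
  g <- create_grid(25, 25, 50)
  set.seed(43)
  rn <- generate_roads_perlin(g, 25, 0, octaves = 2, persistence = 0.5,
                              cone_angle = 90, dist_weight = 1)
  pl <- rn$polylines[[1]]
  # reconstruct the walked cells; the end of the walk is its target/boundary
  end <- pl[nrow(pl), ]
  d <- sqrt((pl[, 1] - end[1])^2 + (pl[, 2] - end[2])^2)
  expect_true(all(diff(d) < 1e-9))
  expect_error(generate_roads_perlin(g, 10, 0, octaves = 0), "octaves")
  expect_error(generate_roads_perlin(g, 10, 0, dist_weight = 2), "dist_weight")
})
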