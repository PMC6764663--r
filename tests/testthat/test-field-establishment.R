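# single-household setup on an otherwise empty grid with one road row
one_household_setup <- function(width = 10, height = 10, expected_cells = 4,
                                cell_m = 100) {
  g <- create_grid(width, height, cell_m)
  rn <- new_roads_for_test(g, spacing = height)
  g$road <- rn$road_mask
  hb <- which(rn$road_mask)[ceiling(sum(rn$road_mask) / 2)]
  hb_xy <- cell_xy(g, hb)
  roster <- data.frame(id = 1L, expected_cells = as.integer(expected_cells),
                       realized_cells = 0L, village = 1L,
                       hb_x = hb_xy[1], hb_y = hb_xy[2], growing = TRUE)
  list(grid = g, roster = roster)
}

test_that("a single household realizes its expected area exactly", {
  s <- one_household_setup(expected_cells = 4)
  cfg <- lgraf_config(setup_type = "households", n_households = 1,
                      hh_area_dist = dist_spec("normal", 4, 0),
                      field_size_dist = dist_spec("normal", 4, 0),
                      cell_length_m = 100)
  set.seed(67)
  est <- establish_all_fields(s$grid, s$roster, cfg)
  expect_equal(nrow(est$fields), 1L)
  expect_equal(est$fields$n_cells, 4L)
  expect_equal(est$roster$realized_cells, 4L)
  expect_false(est$roster$growing)
  expect_equal(sum(s$grid$landcover == 1L), 4L)
})

test_that("the improvement rule stops growth only when overshoot worsens", {
  # E = 14, constant field size 3: 12 + 3 -> |15-14| = 1 < |12-14| = 2, so a
  # fifth field is taken and the household ends at 15 cells
  s <- one_household_setup(width = 12, height = 12, expected_cells = 14)
  cfg <- lgraf_config(setup_type = "households", n_households = 1,
                      hh_area_dist = dist_spec("normal", 14, 0),
                      field_size_dist = dist_spec("normal", 3, 0),
                      cell_length_m = 100)
  set.seed(71)
  est <- establish_all_fields(s$grid, s$roster, cfg)
  expect_equal(est$roster$realized_cells, 15L)
  # E = 13: 12 + 3 -> |15-13| = 2 > |12-13| = 1, so growth stops at 12
  s <- one_household_setup(width = 12, height = 12, expected_cells = 13)
  set.seed(71)
  est <- establish_all_fields(s$grid, s$roster, cfg)
  expect_equal(est$roster$realized_cells, 12L)
})

test_that("failed tries advance the strategy and finally exhaust", {
  g <- create_grid(5, 5, 100)
  g$landcover[] <- 1L  # fully occupied: every search fails
  g$owner[] <- 99L; g$field[] <- 1L
  cfg <- lgraf_config(setup_type = "households", n_households = 1,
                      strategies = c("s1", "s3"), change_strategy = 2L,
                      cell_length_m = 100)
  hh <- list(id = 1L, hb_x = 2L, hb_y = 2L, origin_x = 2L, origin_y = 2L,
             own_cells = integer(0), strategy_index = 1L, failed_tries = 0L)
  r1 <- attempt_field_establishment(g, hh, 2L, cfg, 1L)
  expect_false(r1$success)
  expect_equal(r1$household$strategy_index, 1L)
  r2 <- attempt_field_establishment(g, r1$household, 2L, cfg, 1L)
  expect_equal(r2$household$strategy_index, 2L)  # switched after exactly 2
  expect_false(r2$exhausted)
  r3 <- attempt_field_establishment(g, r2$household, 2L, cfg, 1L)
  r4 <- attempt_field_establishment(g, r3$household, 2L, cfg, 1L)
  expect_true(r4$exhausted)
  expect_equal(r4$household$strategy_index, 1L)  # reset for a fresh size
})

test_that("the home-base search starts at the distance-1 ring", {
  g <- create_grid(9, 9, 100)
  hh <- list(id = 1L, hb_x = 4L, hb_y = 4L, origin_x = 4L, origin_y = 4L,
             own_cells = integer(0))
  set.seed(73)
  for (i in 1:10) {
    cell <- find_start_cell(g, hh, "s1")
    expect_equal(abs(cell[1] - 4L) + abs(cell[2] - 4L), 1L)  # a rook neighbor
  }
})

test_that("the nearest-cell searches match an exhaustive scan", {
  set.seed(79)
  for (i in 1:20) {
    g <- create_grid(20, 20, 100)
    occ <- sample(400, 150)
    g$landcover[occ] <- 1L; g$owner[occ] <- 1L; g$field[occ] <- 1L
    hb <- sample(setdiff(1:400, occ), 1)
    xy <- cell_xy(g, hb)
    hh <- list(id = 2L, hb_x = xy[1], hb_y = xy[2], origin_x = xy[1],
               origin_y = xy[2], own_cells = integer(0))
    cell <- find_start_cell(g, hh, "s1")
    free <- setdiff(which(g$landcover == 0L), hb)
    fxy <- cell_xy(g, free)
    dmin <- min((fxy[, 1] - xy[1])^2 + (fxy[, 2] - xy[2])^2)
    expect_equal((cell[1] - xy[1])^2 + (cell[2] - xy[2])^2, dmin)
  }
})

test_that("s2 needs own fields and s4 needs isolated others-cells", {
  g <- create_grid(6, 6, 100)
  hh <- list(id = 1L, hb_x = 2L, hb_y = 2L, origin_x = 2L, origin_y = 2L,
             own_cells = integer(0))
  expect_null(find_start_cell(g, hh, "s2"))
  # checkerboard of fields: every others-cell touches a field
  idx <- which((row(g$landcover) + col(g$landcover)) %% 2 == 0)
  g$landcover[idx] <- 1L; g$owner[idx] <- 1L; g$field[idx] <- 1L
  expect_null(find_start_cell(g, hh, "s4"))
  expect_false(is.null(find_start_cell(g, hh, "s3")))
})

test_that("field rectangles follow the shape-factor construction", {
  g <- create_grid(20, 20, 100)
  set.seed(83)
  span <- function(cells) {
    xy <- cell_xy(g, cells)
    c(diff(range(xy[, 1])) + 1, diff(range(xy[, 2])) + 1)
  }
  expect_setequal(span(propose_field_cells(g, c(10, 10), 4, 1)), c(2, 2))
  expect_setequal(span(propose_field_cells(g, c(10, 10), 8, 4)), c(1, 8))
  expect_setequal(span(propose_field_cells(g, c(10, 10), 6, 1)), c(2, 3))
  expect_length(propose_field_cells(g, c(10, 10), 6, 1), 6L)
  # corner fallback: start in the top-right corner still succeeds
  expect_length(propose_field_cells(g, c(19, 19), 4, 1), 4L)
  # no room: occupied ring around the start
  g2 <- create_grid(5, 5, 100)
  ring <- which(!(row(g2$landcover) == 3 & col(g2$landcover) == 3))
  g2$landcover[ring] <- 1L; g2$owner[ring] <- 1L; g2$field[ring] <- 1L
  expect_null(propose_field_cells(g2, c(2, 2), 2, 1))
})

test_that("ownership is exclusive and areas are conserved", {
  res <- small_landscape(seed = 9, prop = 0.3)
  g <- res$grid
  expect_true(validate_grid(g, res$config$households_per_cell))
  expect_equal(sum(res$roster$realized_cells), sum(g$landcover == 1L))
  expect_equal(sum(res$fields$n_cells), sum(g$landcover == 1L))
  # per-household cell counts agree with the owner layer
  own_counts <- table(factor(g$owner[g$owner >= 0],
                             levels = res$roster$id))
  expect_equal(as.integer(own_counts), res$roster$realized_cells)
  # every field is one 8-connected patch of its own cells
  for (fi in sample(seq_along(res$field_cells), 20)) {
    m <- matrix(FALSE, g$height, g$width)
    m[res$field_cells[[fi]]] <- TRUE
    expect_equal(label_patches(m, 8)$n, 1L)
  }
})

test_that("realized sizes recover the configured distributions at low density", {
  # households span several cells so the +/- 1 cell stopping granularity of
  # the improvement rule stays small relative to the mean
  hh_mean_ha <- 2; field_mean_ha <- 0.5  # 8 and 2 cells at 50 m
  real_hh <- c(); real_field <- c()
  for (s in 1:100) {
    res <- small_landscape(seed = s, prop = 0.25,
                           hh_area_dist = dist_spec("log-normal", hh_mean_ha, 0.8),
                           field_size_dist = dist_spec("log-normal", field_mean_ha, 0.2))
    real_hh <- c(real_hh, res$roster$realized_cells)
    real_field <- c(real_field, res$fields$n_cells)
  }
  cell_ha <- 0.25
  expect_lt(abs(mean(real_hh) * cell_ha - hh_mean_ha) / hh_mean_ha, 0.05)
  expect_lt(abs(mean(real_field) * cell_ha - field_mean_ha) / field_mean_ha, 0.05)
})

test_that("higher shape factors give less compact fields", {
  mean_compactness <- function(sf) {
    vals <- c()
    for (s in 1:10) {
      res <- small_landscape(seed = s, prop = 0.2, width = 30, height = 30,
                             field_shape_factor = sf,
                             hh_area_dist = dist_spec("normal", 8, 0),
                             field_size_dist = dist_spec("normal", 4, 0))
      for (cells in res$field_cells) {
        m <- matrix(FALSE, 30, 30)
        m[cells] <- TRUE
        pg <- patch_geometry(m, 8)
        vals <- c(vals, sum(pg$perimeter_edges)^2 / sum(pg$area_cells))
      }
    }
    mean(vals)
  }
  comp <- c(mean_compactness(1), mean_compactness(2), mean_compactness(4))
  expect_true(all(diff(comp) > 0))
})
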