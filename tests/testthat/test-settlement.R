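const_hh <- function(mean_ha) dist_spec("normal", mean_ha, 0)  # sd 0 = constant

test_that("the roster realizes the three setup types", {
  g <- create_grid(100, 100, 50)
  cfg <- lgraf_config(setup_type = "households", n_households = 10,
                      hh_area_dist = const_hh(1),
                      vlg_size_dist = dist_spec("constant", 5))
  set.seed(47)
  r <- build_household_roster(cfg, g)
  expect_equal(nrow(r), 10L)
  expect_true(all(r$expected_cells == 4L))  # 1 ha on 0.25 ha cells
  expect_equal(as.integer(table(r$village)), c(5L, 5L))

  cfg <- lgraf_config(setup_type = "villages", n_villages = 2,
                      hh_area_dist = const_hh(1),
                      vlg_size_dist = dist_spec("constant", 3))
  r <- build_household_roster(cfg, g)
  expect_equal(nrow(r), 6L)
  expect_equal(length(unique(r$village)), 2L)

  cfg <- lgraf_config(setup_type = "area", prop_agri_area = 0.5,
                      hh_area_dist = const_hh(2.5))
  r <- build_household_roster(cfg, g)
  expect_equal(nrow(r), 500L)  # 1250 ha / 2.5 ha
})

test_that("area-setup expected totals cover the target minimally", {
  g <- create_grid(50, 50, 50)
  cfg <- lgraf_config(setup_type = "area", prop_agri_area = 0.4,
                      hh_area_dist = dist_spec("log-normal", 2, 1))
  for (s in 1:20) {
    set.seed(s)
    r <- build_household_roster(cfg, g)
    target <- 0.4 * 2500
    expect_gte(sum(r$expected_cells), target)
    expect_lt(sum(r$expected_cells) - max(r$expected_cells), target)
  }
})

test_that("same seed reproduces roster, villages and home-bases exactly", {
  cfg <- lgraf_config(setup_type = "area", prop_agri_area = 0.3, width = 40,
                      height = 40, total_road_length = 160)
  a <- lgraf_generate(cfg, seed_override = 5)
  b <- lgraf_generate(cfg, seed_override = 5)
  expect_identical(a$roster, b$roster)
  expect_identical(a$villages, b$villages)
})

test_that("village centers sit on roads at the required spacing", {
  g <- create_grid(100, 100, 50)
  set.seed(53)
  rn <- generate_roads_graffe(g, 800, 5)
  roster <- data.frame(id = 1:25, village = rep(1:5, each = 5))
  for (s in 1:50) {
    set.seed(s)
    v <- place_villages(roster, rn$road_mask, 10, g)
    expect_equal(nrow(v), 5L)
    expect_true(all(rn$road_mask[v$x * g$height + v$y + 1L]))
    dmat <- as.matrix(dist(v[, c("x", "y")]))
    expect_true(all(dmat[upper.tri(dmat)] >= 10))
  }
  # infeasible spacing: relaxed with a warning, centers still on roads
  expect_warning(v <- place_villages(data.frame(id = 1:2, village = c(1, 2)),
                                     rn$road_mask, 1000, g), "relaxed")
  expect_true(all(rn$road_mask[v$x * g$height + v$y + 1L]))
  expect_error(place_villages(roster, matrix(FALSE, 100, 100), 1, g),
               "no road cells")
})

test_that("home-bases respect the per-cell cap and cluster near centers", {
  g <- create_grid(50, 50, 50)
  set.seed(59)
  rn <- generate_roads_graffe(g, 300, 3)
  mk_roster <- function(n) data.frame(id = seq_len(n), village = 1L,
                                      hb_x = NA_integer_, hb_y = NA_integer_)
  v <- place_villages(mk_roster(1), rn$road_mask, 0, g)
  # cap 1 with k households: k distinct home-base cells
  g1 <- create_grid(50, 50, 50)
  r <- place_homebases(mk_roster(20), v, rn$road_mask, 1, g1)
  expect_equal(max(g1$homebase), 1L)
  expect_equal(sum(g1$homebase), 20L)
  expect_equal(nrow(unique(r[, c("hb_x", "hb_y")])), 20L)
  # tighter caps spread households farther from the center
  mean_dist <- function(cap, seed) {
    set.seed(seed)
    gg <- create_grid(50, 50, 50)
    rr <- place_homebases(mk_roster(30), v, rn$road_mask, cap, gg)
    expect_true(all(gg$homebase <= cap))
    mean(sqrt((rr$hb_x - v$x)^2 + (rr$hb_y - v$y)^2))
  }
  d2 <- sapply(1:20, function(s) mean_dist(2, s))
  d30 <- sapply(1:20, function(s) mean_dist(30, s))
  expect_lt(mean(d30), mean(d2))
  # capacity error
  expect_error(place_homebases(mk_roster(500), v,
                               rn$road_mask & FALSE | (g$landcover == 99), 1, g),
               "capacity")
})

test_that("sampled village sizes match the configured mean", {
  g <- create_grid(100, 100, 50)
  cfg <- lgraf_config(setup_type = "households", n_households = 60,
                      hh_area_dist = dist_spec("log-normal", 2, 1),
                      vlg_size_dist = dist_spec("normal", 12, 3))
  sizes <- unlist(lapply(1:200, function(s) {
    set.seed(s)
    r <- build_household_roster(cfg, g)
    tab <- table(r$village)
    tab[-length(tab)]  # last village absorbs the remainder
  }))
  se <- 3 / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - 12), 3 * se + 0.5)  # + rounding granularity
})
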