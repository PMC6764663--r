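# Independent brute-force oracles, deliberately written in a different style
# from the package implementations they check.

# stack-based flood fill, one cell at a time
flood_fill_oracle <- function(mask, connectivity) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 4) {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  } else {
    dr <- c(-1, 1, 0, 0, -1, -1, 1, 1); dc <- c(0, 0, -1, 1, -1, 1, -1, 1)
  }
  n <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    n <- n + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- n
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_along(dr)) {
        r <- p[1] + dr[k]; c <- p[2] + dc[k]
        if (r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- n
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  list(labels = lab, n = n)
}

# per-patch perimeter by iterating every cell and its four neighbors
perimeter_oracle <- function(mask, labels, n) {
  h <- nrow(mask); w <- ncol(mask)
  per <- integer(n)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!mask[r, c]) next
    l <- labels[r, c]
    for (k in 1:4) {
      r2 <- r + c(-1, 1, 0, 0)[k]; c2 <- c + c(0, 0, -1, 1)[k]
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w || !mask[r2, c2])
        per[l] <- per[l] + 1L
    }
  }
  per
}

# closed-box segment intersection test, cell by cell (slab clipping)
segment_hits_box <- function(p0, p1, xlo, xhi, ylo, yhi) {
  d <- p1 - p0
  tmin <- 0; tmax <- 1
  for (ax in 1:2) {
    lo <- c(xlo, ylo)[ax]; hi <- c(xhi, yhi)[ax]
    if (abs(d[ax]) < 1e-12) {
      if (p0[ax] < lo - 1e-9 || p0[ax] > hi + 1e-9) return(FALSE)
    } else {
      t1 <- (lo - p0[ax]) / d[ax]; t2 <- (hi - p0[ax]) / d[ax]
      if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
      tmin <- max(tmin, t1); tmax <- min(tmax, t2)
      if (tmin > tmax + 1e-9) return(FALSE)
    }
  }
  TRUE
}

supercover_oracle <- function(polylines, grid) {
  cs <- grid$cell_length_m
  mask <- matrix(FALSE, grid$height, grid$width)
  for (pl in polylines) {
    for (s in seq_len(nrow(pl) - 1L)) {
      for (x in 0:(grid$width - 1L)) for (y in 0:(grid$height - 1L)) {
        if (mask[y + 1, x + 1]) next
        if (segment_hits_box(pl[s, ], pl[s + 1L, ],
                             x * cs, (x + 1) * cs, y * cs, (y + 1) * cs))
          mask[y + 1, x + 1] <- TRUE
      }
    }
  }
  mask
}

# deterministic horizontal road grid, no RNG involved
new_roads_for_test <- function(grid, spacing = 10) {
  cs <- grid$cell_length_m
  ys <- seq(spacing %/% 2, grid$height - 1, by = spacing)
  pls <- lapply(ys, function(y)
    rbind(c(0, (y + 0.5) * cs), c(grid$width * cs, (y + 0.5) * cs)))
  new_road_network(pls, grid)
}

# two-crop test configuration used across suites
two_crop_config <- function(..., specialization = c(0, 0),
                            mode = "landscape-level-fraction") {
  lgraf_config(...,
    crops = data.frame(name = c("oilpalm", "rubber"), fraction = c(0.5, 0.5),
                       specialization = specialization),
    land_use_assignment = mode)
}

# compact landscape used where only a finished pipeline state is needed
small_landscape <- function(seed = 1, prop = 0.25, width = 40, height = 40, ...) {
  cfg <- lgraf_config(setup_type = "area", prop_agri_area = prop,
                      width = width, height = height,
                      total_road_length = 4 * width, min_dist_roads = 4,
                      vlg_size_dist = dist_spec("constant", 8),
                      vlg_min_distance = 5, ...)
  lgraf_generate(cfg, seed_override = seed)
}
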