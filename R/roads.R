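# Road networks. Roads are dimensionless polylines in landscape coordinates
# (meters); the derived road mask flags every cell whose closed square is
# intersected by at least one polyline (supercover rasterization, so no
# diagonal gaps appear along a line).

new_road_network <- function(polylines, grid) {
  mask <- rasterize_roads(polylines, grid)
  structure(list(polylines = polylines, road_mask = mask,
                 total_road_cells = sum(mask)),
            class = "lgraf_roads")
}

#' @export
print.lgraf_roads <- function(x, ...) {
  cat(sprintf("<road network: %d polylines, %d road cells>\n",
              length(x$polylines), x$total_road_cells))
  invisible(x)
}

# all cells whose closed square contains the point (px, py); up to 4 when
# the point sits on a cell corner
cells_containing_point <- function(grid, px, py) {
  cs <- grid$cell_length_m
  one_axis <- function(p, nmax) {
    u <- p / cs
    r <- round(u)
    ks <- if (abs(u - r) < 1e-9) c(r - 1, r) else floor(u)
    ks[ks >= 0 & ks < nmax]
  }
  xs <- one_axis(px, grid$width)
  ys <- one_axis(py, grid$height)
  if (!length(xs) || !length(ys)) return(NULL)
  cbind(x = rep(xs, each = length(ys)), y = rep(ys, times = length(xs)))
}

#' Rasterize polylines onto the grid
#'
#' Supercover traversal: a cell is flagged iff some segment intersects its
#' closed square, including pure corner touches. Deterministic.
#'
#' @param polylines list of n x 2 numeric matrices of vertex coordinates in
#'   meters (landscape frame).
#' @param grid an `lgraf_grid`.
#' @return logical height x width matrix.
#' @export
rasterize_roads <- function(polylines, grid) {
  mask <- matrix(FALSE, grid$height, grid$width)
  cs <- grid$cell_length_m
  flag <- function(cells) {
    if (!is.null(cells) && nrow(cells))
      mask[cells[, 1L] * grid$height + cells[, 2L] + 1L] <<- TRUE
  }
  for (pl in polylines) {
    if (is.null(dim(pl))) pl <- matrix(pl, ncol = 2, byrow = TRUE)
    nv <- nrow(pl)
    if (nv == 1L) { flag(cells_containing_point(grid, pl[1, 1], pl[1, 2])); next }
    for (s in seq_len(nv - 1L)) {
      x0 <- pl[s, 1]; y0 <- pl[s, 2]; x1 <- pl[s + 1L, 1]; y1 <- pl[s + 1L, 2]
      dx <- x1 - x0; dy <- y1 - y0
      ts <- c(0, 1)
      if (abs(dx) > 0) {
        ks <- seq(ceiling(min(x0, x1) / cs), floor(max(x0, x1) / cs))
        ts <- c(ts, (ks * cs - x0) / dx)
      }
      if (abs(dy) > 0) {
        ks <- seq(ceiling(min(y0, y1) / cs), floor(max(y0, y1) / cs))
        ts <- c(ts, (ks * cs - y0) / dy)
      }
      ts <- sort(unique(pmin(1, pmax(0, ts))))
      # sample the segment at every crossing and between crossings
      probe <- sort(c(ts, (ts[-1] + ts[-length(ts)]) / 2))
      for (t in probe)
        flag(cells_containing_point(grid, x0 + t * dx, y0 + t * dy))
    }
  }
  mask
}

#' Load a road network from a vector file
#'
#' Reads line geometries from a GeoJSON file (LineString / MultiLineString,
#' as Feature, FeatureCollection or bare geometry), maps them into the
#' landscape frame by an affine fit of the data bounding box onto the grid
#' extent, and derives the road-cell mask with [rasterize_roads()].
#'
#' @param path path to a GeoJSON line layer.
#' @param grid an `lgraf_grid`.
#' @return an `lgraf_roads` object.
#' @export
load_road_vector <- function(path, grid) {
  if (!file.exists(path)) stop("load_road_vector: cannot read ", path,
                               call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lines <- list()
  grab_geom <- function(geom) {
    if (is.null(geom$type)) return()
    if (geom$type == "LineString") {
      lines[[length(lines) + 1L]] <<-
        do.call(rbind, lapply(geom$coordinates, function(p)
          c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    } else if (geom$type == "MultiLineString") {
      for (part in geom$coordinates)
        lines[[length(lines) + 1L]] <<-
          do.call(rbind, lapply(part, function(p)
            c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    }
  }
  if (identical(doc$type, "FeatureCollection")) {
    for (f in doc$features) grab_geom(f$geometry)
  } else if (identical(doc$type, "Feature")) {
    grab_geom(doc$geometry)
  } else grab_geom(doc)
  if (!length(lines))
    stop("load_road_vector: no line geometries in ", path, call. = FALSE)
  all_xy <- do.call(rbind, lines)
  rng_x <- range(all_xy[, 1]); rng_y <- range(all_xy[, 2])
  if (diff(rng_x) == 0 || diff(rng_y) == 0)
    stop("load_road_vector: degenerate (zero-extent) bounding box", call. = FALSE)
  ext_x <- grid$width * grid$cell_length_m
  ext_y <- grid$height * grid$cell_length_m
  fitted <- lapply(lines, function(pl) cbind(
    (pl[, 1] - rng_x[1]) / diff(rng_x) * ext_x,
    (pl[, 2] - rng_y[1]) / diff(rng_y) * ext_y))
  new_road_network(fitted, grid)
}

#' Generate straight axis-aligned roads
#'
#' Straight-road creation: full-span horizontal or vertical roads with
#' alternating orientation (the first orientation is random), each road's
#' offset drawn uniformly among the rows/columns at distance at least
#' `min_dist` from all same-orientation roads. Roads are appended until the
#' road-cell total reaches `total_road_length` or no admissible offset
#' remains (a shortfall is reported as a message).
#'
#' @param grid an `lgraf_grid`.
#' @param total_road_length target number of road cells (<= half the cells).
#' @param min_dist minimum offset distance in cells between same-orientation
#'   roads.
#' @return an `lgraf_roads` object.
#' @export
generate_roads_graffe <- function(grid, total_road_length, min_dist = 0) {
  stopifnot(total_road_length >= 0, min_dist >= 0)
  if (total_road_length > 0.5 * grid$width * grid$height)
    stop("generate_roads_graffe: total_road_length exceeds half the landscape",
         call. = FALSE)
  cs <- grid$cell_length_m
  polylines <- list()
  used <- list(h = integer(0), v = integer(0))
  horiz <- stats::runif(1) < 0.5
  mask <- matrix(FALSE, grid$height, grid$width)
  road_cells <- 0L
  repeat {
    if (total_road_length == 0L || road_cells >= total_road_length) break
    placed <- FALSE
    for (try_orient in 1:2) {
      if (horiz) {
        cand <- setdiff(0:(grid$height - 1L), unlist(lapply(used$h, function(o)
          seq(o - ceiling(min_dist) + 1L, o + ceiling(min_dist) - 1L))))
        cand <- cand[cand >= 0 & cand < grid$height]
        if (length(cand)) {
          y <- if (length(cand) == 1L) cand else sample(cand, 1L)
          used$h <- c(used$h, y)
          polylines[[length(polylines) + 1L]] <-
            rbind(c(0, (y + 0.5) * cs), c(grid$width * cs, (y + 0.5) * cs))
          placed <- TRUE
        }
      } else {
        cand <- setdiff(0:(grid$width - 1L), unlist(lapply(used$v, function(o)
          seq(o - ceiling(min_dist) + 1L, o + ceiling(min_dist) - 1L))))
        cand <- cand[cand >= 0 & cand < grid$width]
        if (length(cand)) {
          x <- if (length(cand) == 1L) cand else sample(cand, 1L)
          used$v <- c(used$v, x)
          polylines[[length(polylines) + 1L]] <-
            rbind(c((x + 0.5) * cs, 0), c((x + 0.5) * cs, grid$height * cs))
          placed <- TRUE
        }
      }
      if (placed) break
      horiz <- !horiz  # no admissible offset: try the other orientation
    }
    if (!placed) {
      message(sprintf("graffe roads: stopped at %d of %d requested road cells (no admissible offset)",
                      road_cells, total_road_length))
      break
    }
    horiz <- !horiz
    mask <- mask | rasterize_roads(polylines[length(polylines)], grid)
    road_cells <- sum(mask)
  }
  new_road_network(polylines, grid)
}

# fractal value-noise elevation in [0, 1], `octaves` layers with amplitude
# decay `persistence`; lattice values are bilinearly interpolated
fractal_elevation <- function(width, height, octaves, persistence) {
  elev <- matrix(0, height, width)
  amp <- 1
  for (o in seq_len(octaves)) {
    period <- max(2, 2^(max(4 - o + 1, 1)))   # halving spatial period per octave
    nx <- ceiling((width - 1) / period) + 2L
    ny <- ceiling((height - 1) / period) + 2L
    lattice <- matrix(stats::runif(nx * ny), ny, nx)
    ux <- (seq_len(width) - 1) / period
    uy <- (seq_len(height) - 1) / period
    ix <- floor(ux); fx <- ux - ix
    iy <- floor(uy); fy <- uy - iy
    sx <- fx * fx * (3 - 2 * fx)   # smoothstep
    sy <- fy * fy * (3 - 2 * fy)
    v00 <- lattice[cbind(rep(iy + 1L, width), rep(ix + 1L, each = height))]
    v01 <- lattice[cbind(rep(iy + 1L, width), rep(ix + 2L, each = height))]
    v10 <- lattice[cbind(rep(iy + 2L, width), rep(ix + 1L, each = height))]
    v11 <- lattice[cbind(rep(iy + 2L, width), rep(ix + 2L, each = height))]
    wx <- rep(sx, each = height); wy <- rep(sy, width)
    layer <- matrix((1 - wy) * ((1 - wx) * v00 + wx * v01) +
                    wy * ((1 - wx) * v10 + wx * v11), height, width)
    elev <- elev + amp * layer
    amp <- amp * persistence
  }
  rng <- range(elev)
  if (diff(rng) == 0) return(matrix(0.5, height, width))
  (elev - rng[1]) / diff(rng)
}

#' Generate roads guided by a random elevation model
#'
#' Builds a fractal-noise elevation field (`octaves` layers, amplitude decay
#' `persistence`), then walks roads across it: a walker starts at a random
#' boundary cell heading inward toward a target on the opposite boundary; at
#' each step the candidate neighbor cells within the forward cone of
#' half-angle `cone_angle/2` are scored
#' `dist_weight * (normalized distance to target) +
#' (1 - dist_weight) * elevation`, and the walker moves to the minimum.
#' A walk ends on reaching the target or the boundary. Further walkers branch
#' from random existing road cells (respecting `min_dist` between branch
#' points where feasible) until the road-cell total reaches
#' `total_road_length`.
#'
#' @inheritParams generate_roads_graffe
#' @param octaves number of noise octaves (>= 1).
#' @param persistence amplitude decay per octave, in (0, 1].
#' @param cone_angle full opening angle of the forward search cone (degrees,
#'   in (0, 180]).
#' @param dist_weight weight in \[0, 1\] of distance-to-target versus
#'   elevation.
#' @return an `lgraf_roads` object.
#' @export
generate_roads_perlin <- function(grid, total_road_length, min_dist = 0,
                                  octaves = 4, persistence = 0.5,
                                  cone_angle = 90, dist_weight = 0.5) {
  if (octaves < 1) stop("generate_roads_perlin: octaves must be >= 1", call. = FALSE)
  if (persistence <= 0 || persistence > 1)
    stop("generate_roads_perlin: persistence must be in (0, 1]", call. = FALSE)
  if (cone_angle <= 0 || cone_angle > 180)
    stop("generate_roads_perlin: cone_angle must be in (0, 180]", call. = FALSE)
  if (dist_weight < 0 || dist_weight > 1)
    stop("generate_roads_perlin: dist_weight must be in [0, 1]", call. = FALSE)
  if (total_road_length > 0.5 * grid$width * grid$height)
    stop("generate_roads_perlin: total_road_length exceeds half the landscape",
         call. = FALSE)
  W <- grid$width; H <- grid$height; cs <- grid$cell_length_m
  if (total_road_length == 0L) return(new_road_network(list(), grid))
  elev <- fractal_elevation(W, H, octaves, persistence)
  half_cone <- cone_angle / 2 * pi / 180
  off <- neighbor_offsets(8)

  boundary_cell <- function() {
    side <- sample(4L, 1L)
    switch(side,
      c(0L, sample(0:(H - 1L), 1L)),
      c(W - 1L, sample(0:(H - 1L), 1L)),
      c(sample(0:(W - 1L), 1L), 0L),
      c(sample(0:(W - 1L), 1L), H - 1L))
  }
  opposite_boundary <- function(start) {
    if (start[1L] == 0L) c(W - 1L, sample(0:(H - 1L), 1L))
    else if (start[1L] == W - 1L) c(0L, sample(0:(H - 1L), 1L))
    else if (start[2L] == 0L) c(sample(0:(W - 1L), 1L), H - 1L)
    else c(sample(0:(W - 1L), 1L), 0L)
  }
  on_boundary <- function(p) p[1L] == 0L || p[1L] == W - 1L ||
    p[2L] == 0L || p[2L] == H - 1L

  walk <- function(start, target) {
    path <- matrix(start, 1L, 2L)
    cur <- start
    heading <- c(target[1L] - start[1L], target[2L] - start[2L])
    heading <- heading / max(sqrt(sum(heading^2)), 1e-12)
    d0 <- max(sqrt(sum((target - start)^2)), 1)
    for (step in seq_len(4L * (W + H))) {
      nx <- cur[1L] + off[, 1L]; ny <- cur[2L] + off[, 2L]
      ok <- nx >= 0L & nx < W & ny >= 0L & ny < H
      nx <- nx[ok]; ny <- ny[ok]
      dirx <- off[ok, 1L]; diry <- off[ok, 2L]
      len <- sqrt(dirx^2 + diry^2)
      cosang <- (dirx * heading[1L] + diry * heading[2L]) / len
      ang <- acos(pmin(1, pmax(-1, cosang)))
      in_cone <- ang <= half_cone + 1e-9
      if (!any(in_cone)) in_cone <- ang <= min(ang) + 1e-9
      nx <- nx[in_cone]; ny <- ny[in_cone]
      dist <- sqrt((nx - target[1L])^2 + (ny - target[2L])^2) / d0
      score <- dist_weight * dist + (1 - dist_weight) * elev[ny * H + nx + 1L]
      k <- which.min(score)
      nxt <- c(nx[k], ny[k])
      heading <- (nxt - cur) / sqrt(sum((nxt - cur)^2))
      cur <- nxt
      path <- rbind(path, cur)
      if (all(cur == target) || (step > 1L && on_boundary(cur))) break
    }
    path
  }

  polylines <- list()
  branch_points <- matrix(numeric(0), 0L, 2L)
  road_cells_mask <- matrix(FALSE, H, W)
  for (w in seq_len(200L)) {
    if (length(polylines) == 0L) {
      start <- boundary_cell()
      target <- opposite_boundary(start)
    } else {
      cand_idx <- which(road_cells_mask)
      if (!length(cand_idx)) break
      # prefer branch points at min_dist from previous branch points
      pick <- NULL
      for (try in seq_len(50L)) {
        idx <- cand_idx[sample.int(length(cand_idx), 1L)]
        p <- c((idx - 1L) %/% H, (idx - 1L) %% H)
        if (!nrow(branch_points) || min(sqrt((branch_points[, 1L] - p[1L])^2 +
                                             (branch_points[, 2L] - p[2L])^2)) >= min_dist) {
          pick <- p; break
        }
      }
      if (is.null(pick)) {
        idx <- cand_idx[sample.int(length(cand_idx), 1L)]
        pick <- c((idx - 1L) %/% H, (idx - 1L) %% H)
      }
      start <- pick
      target <- boundary_cell()
      if (all(target == start)) target <- opposite_boundary(boundary_cell())
    }
    branch_points <- rbind(branch_points, start)
    path <- walk(start, target)
    polylines[[length(polylines) + 1L]] <- cbind((path[, 1L] + 0.5) * cs,
                                                 (path[, 2L] + 0.5) * cs)
    road_cells_mask <- road_cells_mask |
      rasterize_roads(polylines[length(polylines)], grid)
    if (sum(road_cells_mask) >= total_road_length) break
  }
  new_road_network(polylines, grid)
}
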