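# Cell lattice and its layers. Cells are addressed as (x, y), 0-based, x is
# the column (0..width-1) and y the row (0..height-1) with the origin at the
# lower-left cell; the world extent is [0, width*cell_length_m) x
# [0, height*cell_length_m) meters, half-open and non-wrapping. Layers are
# stored as height x width matrices, m[y + 1, x + 1]; the grid object is
# environment-backed so pipeline stages mutate it in place.

LC_OTHERS <- 0L
LC_FIELD  <- 1L
LC_INACC  <- 2L

#' Create an empty landscape grid
#'
#' The landscape starts completely covered by cells of the aggregate class
#' "others" (forest, grassland, water, degraded land), with no roads, owners,
#' fields, crops or home-bases.
#'
#' @param width,height extent in cells (>= 1).
#' @param cell_length_m side length of one cell in meters.
#' @return an environment-backed object of class `lgraf_grid` with integer
#'   layers `landcover` (0 = others, 1 = field, 2 = inaccessible), `owner`
#'   (-1 = unowned), `field` (-1 = none), `crop` (-1 = none), logical `road`,
#'   and integer `homebase` (home-base count per cell).
#' @export
create_grid <- function(width, height, cell_length_m = 50) {
  if (width < 1 || height < 1) stop("create_grid: dimensions must be >= 1",
                                    call. = FALSE)
  if (cell_length_m <= 0) stop("create_grid: cell_length_m must be positive",
                               call. = FALSE)
  g <- new.env(parent = emptyenv())
  g$width <- as.integer(width)
  g$height <- as.integer(height)
  g$cell_length_m <- as.numeric(cell_length_m)
  dim <- c(g$height, g$width)
  g$landcover <- matrix(LC_OTHERS, dim[1], dim[2])
  g$owner <- matrix(-1L, dim[1], dim[2])
  g$field <- matrix(-1L, dim[1], dim[2])
  g$crop <- matrix(-1L, dim[1], dim[2])
  g$road <- matrix(FALSE, dim[1], dim[2])
  g$homebase <- matrix(0L, dim[1], dim[2])
  class(g) <- "lgraf_grid"
  g
}

#' @export
print.lgraf_grid <- function(x, ...) {
  cat(sprintf("<lgraf_grid %d x %d cells, %g m (%g ha); %d field, %d road, %d inaccessible cells>\n",
              x$width, x$height, x$cell_length_m,
              x$width * x$height * (x$cell_length_m / 100)^2,
              sum(x$landcover == LC_FIELD), sum(x$road),
              sum(x$landcover == LC_INACC)))
  invisible(x)
}

#' Total landscape area in hectares
#' @param grid an `lgraf_grid`.
#' @export
grid_area_ha <- function(grid) {
  grid$width * grid$height * (grid$cell_length_m / 100)^2
}

# linear index <-> coordinates (column-major, matching R matrix storage)
cell_index <- function(grid, x, y) x * grid$height + y + 1L
cell_xy <- function(grid, idx) {
  cbind(x = (idx - 1L) %/% grid$height, y = (idx - 1L) %% grid$height)
}

# shift a matrix by (dx, dy) cells, padding with `fill`; used for neighbor
# queries (positive dx looks to the right neighbor etc.)
shift_layer <- function(m, dx, dy, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  xs <- seq_len(w); ys <- seq_len(h)
  sx <- xs - dx; sy <- ys - dy
  okx <- sx >= 1 & sx <= w; oky <- sy >= 1 & sy <= h
  out[ys[oky], xs[okx]] <- m[sy[oky], sx[okx]]
  out
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4)
    cbind(dx = c(1L, -1L, 0L, 0L), dy = c(0L, 0L, 1L, -1L))
  else
    cbind(dx = c(1L, -1L, 0L, 0L, 1L, 1L, -1L, -1L),
          dy = c(0L, 0L, 1L, -1L, 1L, -1L, 1L, -1L))
}

#' Label connected patches of a mask
#'
#' Connected-component labelling over a boolean layer; cells sharing a label
#' are connected under the chosen adjacency (4 = rook, 8 = queen). Labels run
#' 1..n in discovery order; non-mask cells get 0.
#'
#' @param mask logical matrix (a grid layer).
#' @param connectivity 4 or 8.
#' @return list with `labels` (integer matrix) and `n` (patch count).
#' @export
label_patches <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  off <- neighbor_offsets(connectivity)
  todo <- which(mask)
  n <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    n <- n + 1L
    labels[seed] <- n
    frontier <- seed
    while (length(frontier)) {
      x <- (frontier - 1L) %/% h
      y <- (frontier - 1L) %% h
      nxt <- integer(0)
      for (k in seq_len(nrow(off))) {
        nx <- x + off[k, 1L]; ny <- y + off[k, 2L]
        ok <- nx >= 0L & nx < w & ny >= 0L & ny < h
        if (!any(ok)) next
        nidx <- nx[ok] * h + ny[ok] + 1L
        nidx <- nidx[mask[nidx] & labels[nidx] == 0L]
        if (length(nidx)) {
          labels[nidx] <- n
          nxt <- c(nxt, nidx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(labels = labels, n = n)
}

#' Cells within a radius of a center cell
#'
#' All in-bounds cells whose center-to-center Euclidean distance (in cells)
#' from `center` is at most `r`, ordered by distance with ties broken by a
#' shuffle drawn from the current random stream. Used by the expanding-radius
#' searches of home-base placement and field establishment.
#'
#' @param grid an `lgraf_grid`.
#' @param center integer vector `c(x, y)` inside the grid.
#' @param r radius in cells (>= 0).
#' @return integer matrix with columns `x`, `y`, one row per cell, including
#'   the center itself first.
#' @export
cells_within_radius <- function(grid, center, r) {
  x0 <- center[1L]; y0 <- center[2L]
  if (x0 < 0 || x0 >= grid$width || y0 < 0 || y0 >= grid$height)
    stop("cells_within_radius: center outside grid", call. = FALSE)
  fr <- floor(r)
  dx <- rep.int(-fr:fr, 2L * fr + 1L)
  dy <- rep(-fr:fr, each = 2L * fr + 1L)
  d2 <- dx^2 + dy^2
  keep <- d2 <= r^2
  xs <- x0 + dx[keep]; ys <- y0 + dy[keep]; d2 <- d2[keep]
  ok <- xs >= 0L & xs < grid$width & ys >= 0L & ys < grid$height
  xs <- xs[ok]; ys <- ys[ok]; d2 <- d2[ok]
  ord <- order(d2, stats::runif(length(d2)))
  cbind(x = as.integer(xs[ord]), y = as.integer(ys[ord]))
}

#' Check the cross-layer invariants of a grid
#'
#' Asserts that ownership, field ids and crops are mutually consistent:
#' a cell has an owner iff it is a field cell, a field id iff it is a field
#' cell, crops only on field cells, home-base counts within the configured
#' cap, and no crops or owners on inaccessible cells.
#'
#' @param grid an `lgraf_grid`.
#' @param homebase_cap optional cap on home-bases per cell to assert.
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
validate_grid <- function(grid, homebase_cap = NULL) {
  fail <- function(...) stop("grid invariant violated: ", ..., call. = FALSE)
  fld <- grid$landcover == LC_FIELD
  if (!all((grid$owner >= 0L) == fld)) fail("owner_id >= 0 <=> landcover field")
  if (!all((grid$field >= 0L) == fld)) fail("field_id >= 0 <=> landcover field")
  if (any(grid$crop >= 0L & grid$field < 0L)) fail("crop on non-field cell")
  if (any(grid$landcover == LC_INACC & grid$owner >= 0L))
    fail("inaccessible cell owned")
  if (!is.null(homebase_cap) && any(grid$homebase > homebase_cap))
    fail("homebase count exceeds cap")
  if (any(grid$homebase < 0L)) fail("negative homebase count")
  invisible(TRUE)
}
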