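# Inaccessible areas: patches (large-scale plantations, protected areas)
# excluded from smallholder field establishment.

# grow a square-based patch of `size` cells from `seed_idx` over cells
# currently of class 'others'; occupied cells are skipped and the patch is
# completed on the nearest available others-cells by expanding search.
# Returns the chosen cell indices or NULL if the landscape is full.
grow_square_patch <- function(grid, seed_idx, size) {
  H <- grid$height
  sx <- (seed_idx - 1L) %/% H
  sy <- (seed_idx - 1L) %% H
  side <- ceiling(sqrt(size))
  # square block anchored at the seed (seed = lower-left corner), trimmed
  # row-major to the exact size
  bx <- rep(sx + 0:(side - 1L), times = side)
  by <- rep(sy + 0:(side - 1L), each = side)
  block <- cbind(bx, by)[seq_len(size), , drop = FALSE]
  ok <- block[, 1L] < grid$width & block[, 2L] < grid$height
  idx <- block[ok, 1L] * H + block[ok, 2L] + 1L
  idx <- idx[grid$landcover[idx] == LC_OTHERS]
  idx <- unique(idx)
  missing <- size - length(idx)
  if (missing > 0L) {
    free <- which(grid$landcover == LC_OTHERS)
    free <- setdiff(free, idx)
    if (length(free) < missing) return(NULL)
    fx <- (free - 1L) %/% H; fy <- (free - 1L) %% H
    d2 <- (fx - sx)^2 + (fy - sy)^2
    ord <- order(d2, stats::runif(length(d2)))
    idx <- c(idx, free[ord[seq_len(missing)]])
  }
  idx
}

#' Carve inaccessible areas into the landscape
#'
#' Draws patch sizes (ha) from the inaccessible-area distribution until the
#' converted cell total reaches `inacc_fraction` of the landscape, then
#' places each patch as a square block grown from a seed cell: a uniform
#' random cell (`inacc_location = "random"`) or a uniform random road cell
#' (`"road-connected"`). Cells already occupied are skipped and the patch
#' completes on the nearest free others-cells. The road flag persists under
#' inaccessible cells; land cover becomes inaccessible. Must run after road
#' creation and before field establishment.
#'
#' @param grid an `lgraf_grid` (mutated).
#' @param roads an `lgraf_roads` object.
#' @param config an [lgraf_config()].
#' @return number of inaccessible cells placed, invisibly.
#' @export
place_inaccessible_areas <- function(grid, roads, config) {
  if (config$inacc_fraction == 0) return(invisible(0L))
  if (any(grid$landcover == LC_FIELD))
    stop("place_inaccessible_areas: must run before field establishment",
         call. = FALSE)
  target_cells <- config$inacc_fraction * grid$width * grid$height
  road_idx <- which(roads$road_mask)
  if (config$inacc_location == "road-connected" && !length(road_idx))
    stop("place_inaccessible_areas: road-connected seeding needs road cells",
         call. = FALSE)
  placed <- 0L
  while (placed < target_cells) {
    size_ha <- sample_sizes(config$inacc_dist, 1L)
    size <- area_ha_to_cells(size_ha, grid$cell_length_m)
    cells <- NULL
    for (try in seq_len(10000L)) {
      seed_idx <- if (config$inacc_location == "road-connected")
        road_idx[sample.int(length(road_idx), 1L)]
      else sample.int(grid$width * grid$height, 1L)
      if (grid$landcover[seed_idx] != LC_OTHERS) next
      cells <- grow_square_patch(grid, seed_idx, size)
      if (!is.null(cells)) break
    }
    if (is.null(cells))
      stop("place_inaccessible_areas: cannot place target area after 10000 attempts",
           call. = FALSE)
    grid$landcover[cells] <- LC_INACC
    placed <- placed + length(cells)
  }
  invisible(placed)
}
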