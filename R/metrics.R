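# Class-level landscape metrics in the FRAGSTATS raster convention:
# landscape shape index (LSI), largest patch index (LPI), mean patch area,
# number of patches and patch cohesion index (PCI), computed on a boolean
# class mask. Patch identification defaults to queen (8) adjacency;
# edge/perimeter accounting always uses rook adjacency and includes the
# landscape boundary.

#' Per-patch area and perimeter
#'
#' Labels the patches of `mask` and counts, for every patch, its cells and
#' its perimeter as the number of rook-adjacent cell edges to non-class
#' cells, including edges on the landscape boundary.
#'
#' @param mask logical class mask (grid layer).
#' @param connectivity patch adjacency, 4 or 8.
#' @return data.frame with columns `patch`, `area_cells`, `perimeter_edges`.
#' @export
patch_geometry <- function(mask, connectivity = 8) {
  lab <- label_patches(mask, connectivity)
  if (lab$n == 0L)
    return(data.frame(patch = integer(0), area_cells = integer(0),
                      perimeter_edges = integer(0)))
  same <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(4L)) {
    o <- neighbor_offsets(4)[k, ]
    same <- same + (shift_layer(mask, o[1L], o[2L], FALSE) & mask)
  }
  edge <- (4L - same)[mask]
  labs <- lab$labels[mask]
  data.frame(patch = seq_len(lab$n),
             area_cells = as.integer(tabulate(labs, lab$n)),
             perimeter_edges = as.integer(
               vapply(split(edge, labs), sum, numeric(1))[as.character(seq_len(lab$n))]))
}

# minimum possible total edge length of n class cells packed maximally
# compactly on a raster
min_edge <- function(n) {
  m <- floor(sqrt(n))
  if (m * m == n) 4 * m
  else if (n <= m * (m + 1)) 4 * m + 2
  else 4 * m + 4
}

#' Class-level landscape metrics
#'
#' Computes the five class-level metrics on a boolean mask over the grid:
#' number of patches, mean patch area (ha), largest patch index
#' (LPI, percent of landscape cells in the largest patch), landscape shape
#' index (LSI, total class edge over the minimum edge of an equally sized
#' maximally compact class) and patch cohesion index (PCI, percent). With an
#' empty mask all metrics are `NA` (undefined) except the zero patch count;
#' PCI is additionally undefined on a one-cell landscape.
#'
#' @param mask logical class mask.
#' @param grid an `lgraf_grid` (for cell area and landscape size).
#' @param connectivity patch adjacency, 4 or 8 (default queen).
#' @return object of class `lgraf_class_metrics`: list with `n_patches`,
#'   `mean_patch_area` (ha), `lpi`, `lsi`, `cohesion`, `class_cells`.
#' @export
compute_class_metrics <- function(mask, grid, connectivity = 8) {
  pg <- patch_geometry(mask, connectivity)
  Z <- grid$width * grid$height
  cell_ha <- (grid$cell_length_m / 100)^2
  n <- nrow(pg)
  cls <- sum(pg$area_cells)
  if (n == 0L) {
    out <- list(n_patches = 0L, mean_patch_area = NA_real_, lpi = NA_real_,
                lsi = NA_real_, cohesion = NA_real_, class_cells = 0L)
  } else {
    E <- sum(pg$perimeter_edges)
    cohesion <- if (Z > 1)
      100 * (1 - sum(pg$perimeter_edges) /
               sum(pg$perimeter_edges * sqrt(pg$area_cells))) / (1 - 1 / sqrt(Z))
    else NA_real_
    out <- list(
      n_patches = n,
      mean_patch_area = cls * cell_ha / n,
      lpi = 100 * max(pg$area_cells) / Z,
      lsi = E / min_edge(cls),
      cohesion = cohesion,
      class_cells = cls)
  }
  structure(out, class = "lgraf_class_metrics")
}

#' @export
print.lgraf_class_metrics <- function(x, ...) {
  cat(sprintf("<class metrics: %d cells in %d patches | LSI %.3f LPI %.2f%% mean area %.3f ha PCI %.2f%%>\n",
              x$class_cells, x$n_patches, x$lsi, x$lpi, x$mean_patch_area,
              x$cohesion))
  invisible(x)
}

#' Metrics table for the standard map classes
#'
#' Convenience wrapper computing the class metrics for the `fields` class,
#' the habitat (`others` excluding road cells, which act as patch
#' separators) class, and each crop class present.
#'
#' @param grid an `lgraf_grid` after crop assignment.
#' @param connectivity patch adjacency, 4 or 8.
#' @return data.frame with columns `class`, `metric`, `value`.
#' @export
landscape_metrics_table <- function(grid, connectivity = 8) {
  masks <- list(fields = grid$landcover == LC_FIELD,
                others = grid$landcover == LC_OTHERS & !grid$road)
  for (cid in sort(unique(grid$crop[grid$crop >= 0L])))
    masks[[paste0("crop", cid)]] <- grid$crop == cid
  rows <- lapply(names(masks), function(cl) {
    m <- compute_class_metrics(masks[[cl]], grid, connectivity)
    data.frame(class = cl,
               metric = c("n.patches", "mean.patch.area", "largest.patch.index",
                          "landscape.shape.index", "patch.cohesion.index",
                          "class.cells"),
               value = c(m$n_patches, m$mean_patch_area, m$lpi, m$lsi,
                         m$cohesion, m$class_cells))
  })
  do.call(rbind, rows)
}
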