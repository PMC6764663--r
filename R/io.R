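# Map products and raster/vector/tabular i/o. All spatial outputs use the
# ESRI ASCII grid format (plain text, readable by standard GIS tools);
# vector fixtures are GeoJSON line layers.

NODATA <- -9999L

#' Render the standard map products
#'
#' Builds the integer map layers of a finished landscape: the composite
#' `land_use` map (0 others, 1 agriculture, 2 inaccessible, 3 road,
#' 4 home-base; display precedence home-base > road > land cover), the
#' `crop_type` map (crop id + 1, 0 for non-field cells), the binary
#' `agri_binary` map, the `field_patches` and `household_patches` maps
#' (field id / owner id + 1, 0 for none), the `habitat_patches` map
#' (labelled patches of others-cells with roads acting as separators) and
#' the `road_mask`.
#'
#' @param grid an `lgraf_grid` after the full pipeline.
#' @return named list of map products; each is a list with `name`, `layer`
#'   (integer matrix) and `legend` (data.frame code/label).
#' @export
render_layers <- function(grid) {
  land_use <- grid$landcover
  land_use[grid$road] <- 3L
  land_use[grid$homebase > 0L] <- 4L
  habitat <- label_patches(grid$landcover == LC_OTHERS & !grid$road, 8)$labels
  prod <- function(name, layer, codes, labels)
    list(name = name, layer = layer,
         legend = data.frame(code = codes, label = labels))
  list(
    land_use = prod("land_use", land_use, 0:4,
                    c("others", "agriculture", "inaccessible", "road", "home-base")),
    crop_type = prod("crop_type", grid$crop + 1L,
                     0:(max(grid$crop) + 1L),
                     c("non-field", paste0("crop", seq_len(max(grid$crop) + 1L)))),
    agri_binary = prod("agri_binary",
                       matrix(as.integer(grid$landcover == LC_FIELD),
                              grid$height, grid$width),
                       0:1, c("non-agriculture", "agriculture")),
    field_patches = prod("field_patches", grid$field + 1L,
                         c(0L, 1L), c("none", "field id + 1")),
    household_patches = prod("household_patches", grid$owner + 1L,
                             c(0L, 1L), c("none", "owner id + 1")),
    habitat_patches = prod("habitat_patches", habitat,
                           c(0L, 1L), c("non-habitat", "patch label")),
    road_mask = prod("road_mask",
                     matrix(as.integer(grid$road), grid$height, grid$width),
                     0:1, c("no road", "road")))
}

#' Write a layer as an ESRI ASCII grid
#'
#' Header lines `ncols`, `nrows`, `xllcorner` (0), `yllcorner` (0),
#' `cellsize` and `NODATA_value` (-9999), then one line per row written
#' top-to-bottom with space-separated integer values; `NA` cells become the
#' NODATA value. The format round-trips bit-exactly through
#' [read_ascii_grid()].
#'
#' @param product a map product from [render_layers()], or an integer matrix.
#' @param path output file path.
#' @param grid an `lgraf_grid` (for the cell size).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(product, path, grid) {
  layer <- if (is.list(product)) product$layer else product
  stopifnot(is.matrix(layer))
  layer[is.na(layer)] <- NODATA
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(layer)),
    paste("nrows", nrow(layer)),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", format(grid$cell_length_m, scientific = FALSE)),
    paste("NODATA_value", NODATA)), con)
  for (r in rev(seq_len(nrow(layer))))   # top row = largest y first
    writeLines(paste(as.integer(layer[r, ]), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any ESRI ASCII grid.
#' @return list with `layer` (integer matrix, row 1 = southernmost row, the
#'   package's internal orientation), `cellsize` and `nodata`; NODATA cells
#'   are `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = lines[-(1:6)], what = numeric(), quiet = TRUE)
  m <- matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == hdr$nodata_value] <- NA_integer_
  list(layer = m, cellsize = hdr$cellsize, nodata = hdr$nodata_value)
}

#' Write a synthetic road-line fixture
#'
#' Deterministic GeoJSON line layers inside the grid extent, for testing the
#' vector-road input path. Style `grid` alternates evenly spaced horizontal
#' and vertical full-span lines; style `random-walk` grows each line from a
#' random boundary point by bounded random segments.
#'
#' @param grid an `lgraf_grid` defining the extent.
#' @param n_lines number of lines (>= 1).
#' @param style `"grid"` or `"random-walk"`.
#' @param seed integer seed making the fixture deterministic.
#' @param path output GeoJSON path.
#' @return `path`, invisibly.
#' @export
generate_road_fixture <- function(grid, n_lines, style = c("grid", "random-walk"),
                                  seed = 1L, path) {
  style <- match.arg(style)
  stopifnot(n_lines >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stage_seed(seed, "fixture"))
  ex <- grid$width * grid$cell_length_m
  ey <- grid$height * grid$cell_length_m
  lines <- vector("list", n_lines)
  if (style == "grid") {
    n_h <- ceiling(n_lines / 2)
    n_v <- n_lines - n_h
    cs <- grid$cell_length_m
    snap <- function(v, lim) pmin(lim - cs / 2, (floor(v / cs) + 0.5) * cs)
    ys <- snap(ey * seq_len(n_h) / (n_h + 1), ey)   # cell-center aligned
    xs <- if (n_v > 0) snap(ex * seq_len(n_v) / (n_v + 1), ex) else numeric(0)
    k <- 0L
    for (y in ys) { k <- k + 1L; lines[[k]] <- rbind(c(0, y), c(ex, y)) }
    for (x in xs) { k <- k + 1L; lines[[k]] <- rbind(c(x, 0), c(x, ey)) }
  } else {
    for (k in seq_len(n_lines)) {
      side <- sample(4L, 1L)
      p <- switch(side,
        c(0, stats::runif(1, 0, ey)), c(ex, stats::runif(1, 0, ey)),
        c(stats::runif(1, 0, ex), 0), c(stats::runif(1, 0, ex), ey))
      pts <- matrix(p, 1L)
      ang <- atan2(ey / 2 - p[2], ex / 2 - p[1])
      for (s in seq_len(10L)) {
        ang <- ang + stats::runif(1, -pi / 4, pi / 4)
        step <- stats::runif(1, 0.05, 0.2) * max(ex, ey)
        p <- pmin(c(ex, ey), pmax(0, p + step * c(cos(ang), sin(ang))))
        pts <- rbind(pts, p)
      }
      lines[[k]] <- pts
    }
  }
  features <- lapply(lines, function(pl) list(
    type = "Feature", properties = list(),
    geometry = list(type = "LineString",
                    coordinates = lapply(seq_len(nrow(pl)), function(i)
                      c(pl[i, 1], pl[i, 2])))))
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
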