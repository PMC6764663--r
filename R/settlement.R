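# Household roster construction under the three setup types, and placement
# of villages and home-bases on the road network.

#' Build the preliminary household roster
#'
#' Samples an expected area (ha, converted to cells) for each household from
#' the household area distribution and assigns village ids by drawing village
#' sizes (households per village) from the village size distribution and
#' filling villages in draw order. The household count follows the setup
#' type: `households` gives exactly `n_households` (the last village absorbs
#' the remainder); `villages` gives exactly `n_villages` villages with the
#' sampled sizes; `area` appends households until the summed expected area
#' reaches `prop_agri_area` of the landscape.
#'
#' @param config an [lgraf_config()].
#' @param grid an `lgraf_grid`.
#' @return data.frame with one row per household: `id`, `expected_cells`,
#'   `realized_cells` (0), `village`, `hb_x`/`hb_y` (NA until
#'   [place_homebases()]), `growing`.
#' @export
build_household_roster <- function(config, grid) {
  cell_ha <- (grid$cell_length_m / 100)^2
  sample_expected <- function(n)
    area_ha_to_cells(sample_sizes(config$hh_area_dist, n), grid$cell_length_m)
  n_hh <- switch(config$setup_type,
    households = as.integer(config$n_households),
    villages = {
      sizes <- pmax(1L, as.integer(round(
        sample_sizes(config$vlg_size_dist, config$n_villages))))
      sum(sizes)
    },
    area = NA_integer_)
  if (config$setup_type == "area") {
    target_cells <- config$prop_agri_area * grid$width * grid$height
    expected <- integer(0)
    while (sum(expected) < target_cells) {
      batch <- max(8L, ceiling((target_cells - sum(expected)) /
                                 max(1, config$hh_area_dist$mean / cell_ha)))
      draws <- sample_expected(batch)
      cs <- sum(expected) + cumsum(draws)
      k <- which(cs >= target_cells)
      expected <- c(expected, if (length(k)) draws[seq_len(k[1L])] else draws)
    }
    n_hh <- length(expected)
  } else {
    expected <- sample_expected(n_hh)
  }
  capacity <- sum(grid$landcover == LC_OTHERS)
  if (sum(expected) > capacity)
    warning(sprintf("expected household area (%d cells) exceeds available space (%d cells); establishment will halt early",
                    sum(expected), capacity))

  # village ids by filling sampled sizes in draw order
  if (config$setup_type == "villages") {
    village <- rep(seq_along(sizes), times = sizes)
  } else {
    village <- integer(n_hh)
    filled <- 0L; vid <- 0L
    while (filled < n_hh) {
      vid <- vid + 1L
      vsize <- max(1L, as.integer(round(sample_sizes(config$vlg_size_dist, 1L))))
      take <- min(vsize, n_hh - filled)
      village[filled + seq_len(take)] <- vid
      filled <- filled + take
    }
  }
  data.frame(id = seq_len(n_hh), expected_cells = as.integer(expected),
             realized_cells = 0L, village = village,
             hb_x = NA_integer_, hb_y = NA_integer_, growing = TRUE)
}

#' Place village centers on the road network
#'
#' One center per distinct village id, sampled uniformly among road cells by
#' rejection so that pairwise center distances respect `vlg_min_distance`
#' (up to 1e4 tries per village; on exhaustion the constraint is relaxed to
#' the largest feasible distance found and a warning is issued).
#'
#' @param roster household roster from [build_household_roster()].
#' @param road_mask logical road layer (from an `lgraf_roads` object).
#' @param vlg_min_distance minimum distance between centers, in cells.
#' @param grid an `lgraf_grid`.
#' @return data.frame with columns `id`, `x`, `y`, `target_size`.
#' @export
place_villages <- function(roster, road_mask, vlg_min_distance, grid) {
  road_idx <- which(road_mask)
  if (!length(road_idx))
    stop("place_villages: no road cells to place villages on", call. = FALSE)
  vids <- sort(unique(roster$village))
  H <- grid$height
  centers <- matrix(NA_integer_, length(vids), 2L)
  for (i in seq_along(vids)) {
    best <- NULL; best_d <- -1; found <- FALSE
    for (try in seq_len(10000L)) {
      idx <- road_idx[sample.int(length(road_idx), 1L)]
      p <- c((idx - 1L) %/% H, (idx - 1L) %% H)
      d <- if (i == 1L) Inf else
        min(sqrt((centers[seq_len(i - 1L), 1L] - p[1L])^2 +
                 (centers[seq_len(i - 1L), 2L] - p[2L])^2))
      if (d >= vlg_min_distance) { best <- p; found <- TRUE; break }
      if (d > best_d) { best_d <- d; best <- p }
    }
    if (!found)
      warning(sprintf("village %d: min distance %.1f relaxed to %.1f (no feasible road cell)",
                      vids[i], vlg_min_distance, best_d))
    centers[i, ] <- best
  }
  data.frame(id = vids, x = centers[, 1L], y = centers[, 2L],
             target_size = as.integer(table(factor(roster$village, vids))))
}

#' Place household home-bases around village centers
#'
#' Each household gets a home-base on a road cell near its village center:
#' road cells are taken in order of distance to the center (ties broken by a
#' seeded shuffle) and a household occupies the nearest cell that still has
#' capacity (fewer than `cap` home-bases). Updates the grid's
#' `homebase` layer and the roster's `hb_x`/`hb_y` in place.
#'
#' @param roster household roster.
#' @param villages village table from [place_villages()].
#' @param road_mask logical road layer.
#' @param cap maximum home-bases per cell.
#' @param grid an `lgraf_grid` (mutated).
#' @return the updated roster.
#' @export
place_homebases <- function(roster, villages, road_mask, cap, grid) {
  road_idx <- which(road_mask)
  n_hh <- nrow(roster)
  if (length(road_idx) * cap < n_hh)
    stop(sprintf("place_homebases: road capacity (%d cells x %d) below household count %d",
                 length(road_idx), cap, n_hh), call. = FALSE)
  H <- grid$height
  rx <- (road_idx - 1L) %/% H
  ry <- (road_idx - 1L) %% H
  for (v in seq_len(nrow(villages))) {
    members <- which(roster$village == villages$id[v])
    if (!length(members)) next
    d2 <- (rx - villages$x[v])^2 + (ry - villages$y[v])^2
    ord <- order(d2, stats::runif(length(d2)))
    slot <- 1L
    for (hh in members) {
      while (slot <= length(ord) && grid$homebase[road_idx[ord[slot]]] >= cap)
        slot <- slot + 1L
      if (slot > length(ord))
        stop("place_homebases: ran out of road-cell capacity", call. = FALSE)
      idx <- road_idx[ord[slot]]
      grid$homebase[idx] <- grid$homebase[idx] + 1L
      roster$hb_x[hh] <- rx[ord[slot]]
      roster$hb_y[hh] <- ry[ord[slot]]
    }
  }
  roster
}
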