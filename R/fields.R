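# Field establishment: the core agent loop. Households draw field sizes and
# try to place rectangular fields near their home-base, switching search
# strategies after repeated failures, until the household-size distribution
# is realized (or, for setup-type 'area', the target agricultural cover is
# reached).

eligible_mask <- function(grid) grid$landcover == LC_OTHERS

#' Find a start cell for a field attempt
#'
#' Implements the four search strategies: `s1` returns the unoccupied
#' others-cell nearest to the home-base; `s2` the one nearest to any cell of
#' the household's own fields (`NULL` if it owns none); `s3` searches with
#' expanding radius from the household's most recent search origin; `s4` is
#' like `s3` but requires the cell and all its in-bounds 8-neighbors to be
#' unoccupied others-cells. Distance ties are broken by a shuffle from the
#' current random stream; `NULL` when no admissible cell exists within the
#' grid diagonal.
#'
#' @param grid an `lgraf_grid`.
#' @param household list with elements `hb_x`, `hb_y`, `origin_x`, `origin_y`
#'   and `own_cells` (integer cell indices of owned field cells).
#' @param strategy one of `"s1"`, `"s2"`, `"s3"`, `"s4"`.
#' @return integer `c(x, y)` or `NULL`.
#' @export
find_start_cell <- function(grid, household, strategy) {
  H <- grid$height
  elig <- which(eligible_mask(grid))
  if (!length(elig)) return(NULL)
  ex <- (elig - 1L) %/% H
  ey <- (elig - 1L) %% H
  if (strategy == "s4") {
    ok_mat <- eligible_mask(grid)
    all_free <- ok_mat
    for (k in seq_len(8L)) {
      o <- neighbor_offsets(8)[k, ]
      all_free <- all_free & shift_layer(ok_mat, o[1L], o[2L], TRUE)
    }
    keep <- all_free[elig]
    if (!any(keep)) return(NULL)
    elig <- elig[keep]; ex <- ex[keep]; ey <- ey[keep]
  }
  d2 <- switch(strategy,
    s1 = (ex - household$hb_x)^2 + (ey - household$hb_y)^2,
    s2 = {
      own <- household$own_cells
      if (!length(own)) return(NULL)
      ox <- (own - 1L) %/% H; oy <- (own - 1L) %% H
      acc <- rep(Inf, length(elig))
      for (i in seq_along(own))
        acc <- pmin(acc, (ex - ox[i])^2 + (ey - oy[i])^2)
      acc
    },
    s3 = ,
    s4 = (ex - household$origin_x)^2 + (ey - household$origin_y)^2)
  # searches expand from the distance-1 ring outward: the anchor cell itself
  # is not a candidate
  pos <- d2 > 0
  if (!any(pos)) return(NULL)
  elig <- elig[pos]; ex <- ex[pos]; ey <- ey[pos]; d2 <- d2[pos]
  k <- order(d2, stats::runif(length(d2)))[1L]
  c(ex[k], ey[k])
}

#' Propose the cells of a rectangular field
#'
#' Builds a rectangle of target width `w = max(1, round(sqrt(size /
#' shape_factor)))` and length `ceiling(size / w)` (shape factor 1 gives
#' compact, nearly square fields; larger values give narrow strips), with
#' random orientation, anchored at `start` and filled row-major to exactly
#' `size_cells`. All proposed cells must be in-bounds, of class others and
#' unowned; otherwise the three other anchor corners are tried, then `NULL`
#' is returned (the free area around the start cell is too small).
#'
#' @param grid an `lgraf_grid`.
#' @param start integer `c(x, y)` start cell.
#' @param size_cells field size in cells (>= 1).
#' @param shape_factor >= 1.
#' @return integer vector of cell indices, or `NULL`.
#' @export
propose_field_cells <- function(grid, start, size_cells, shape_factor = 1) {
  stopifnot(size_cells >= 1, shape_factor >= 1)
  H <- grid$height
  w <- max(1L, as.integer(round(sqrt(size_cells / shape_factor))))
  l <- as.integer(ceiling(size_cells / w))
  horizontal <- stats::runif(1) < 0.5   # length along x when horizontal
  rows <- rep(0:(w - 1L), each = l)
  cols <- rep(0:(l - 1L), times = w)
  if (horizontal) { ox <- cols; oy <- rows } else { ox <- rows; oy <- cols }
  ox <- ox[seq_len(size_cells)]; oy <- oy[seq_len(size_cells)]
  for (corner in list(c(1L, 1L), c(-1L, 1L), c(1L, -1L), c(-1L, -1L))) {
    xs <- start[1L] + corner[1L] * ox
    ys <- start[2L] + corner[2L] * oy
    if (any(xs < 0L | xs >= grid$width | ys < 0L | ys >= grid$height)) next
    idx <- xs * H + ys + 1L
    if (all(grid$landcover[idx] == LC_OTHERS)) return(idx)
  }
  NULL
}

#' One field-establishment try for a household
#'
#' Picks a start cell with the household's current strategy, proposes the
#' field rectangle there and, on success, marks the cells on the grid
#' (land cover, owner, field id) and resets the failure counter. On failure
#' the counter is incremented; after `change_strategy` failures the household
#' advances to the next strategy in the list, and once the last strategy has
#' failed that often the try returns failure-with-exhaustion (the caller then
#' draws a new field size). The search origin used by strategies s3/s4 is
#' updated to the tried start cell.
#'
#' @param grid an `lgraf_grid` (mutated on success).
#' @param household list with `id`, `hb_x`, `hb_y`, `origin_x`, `origin_y`,
#'   `own_cells`, `strategy_index`, `failed_tries`.
#' @param size_cells field size in cells.
#' @param config an [lgraf_config()] (strategy list, change-strategy count,
#'   field shape factor).
#' @param field_id id to assign on success.
#' @return list with `success`, `exhausted`, `cells` (indices or `NULL`) and
#'   the updated `household`.
#' @export
attempt_field_establishment <- function(grid, household, size_cells, config,
                                        field_id) {
  strategies <- config$strategies
  strategy <- strategies[household$strategy_index]
  start <- find_start_cell(grid, household, strategy)
  cells <- if (is.null(start)) NULL else
    propose_field_cells(grid, start, size_cells, config$field_shape_factor)
  if (!is.null(start)) {
    household$origin_x <- start[1L]
    household$origin_y <- start[2L]
  }
  if (!is.null(cells)) {
    grid$landcover[cells] <- LC_FIELD
    grid$owner[cells] <- household$id
    grid$field[cells] <- field_id
    household$own_cells <- c(household$own_cells, cells)
    household$failed_tries <- 0L
    return(list(success = TRUE, exhausted = FALSE, cells = cells,
                household = household))
  }
  household$failed_tries <- household$failed_tries + 1L
  exhausted <- FALSE
  if (household$failed_tries >= config$change_strategy) {
    household$failed_tries <- 0L
    household$strategy_index <- household$strategy_index + 1L
    if (household$strategy_index > length(strategies)) {
      household$strategy_index <- 1L
      exhausted <- TRUE
    }
  }
  list(success = FALSE, exhausted = exhausted, cells = NULL,
       household = household)
}

#' Run the full field-establishment loop
#'
#' Loops over all still-growing households in seeded random order. Each turn
#' a household draws a field size `f` from the field-size distribution (for
#' field type `percentage` the distribution mean is first set to
#' `field_size_percentage` times the household-area mean) and, with realized
#' area `R` and expected area `E`, attempts establishment if `R + f < E`, or
#' if the absolute difference to `E` shrinks (`|R + f - E| < |R - E|`);
#' otherwise it stops growing. Failed tries cycle through the strategy list;
#' after full exhaustion a new size is drawn, and three consecutive exhausted
#' sizes retire the household. For setup-type `area` the loop also halts as
#' soon as the total field cover reaches the configured agricultural
#' proportion (checked after every established field, so overshoot is at most
#' one field).
#'
#' @param grid an `lgraf_grid` (mutated).
#' @param roster household roster with placed home-bases.
#' @param config an [lgraf_config()].
#' @return list with the updated `roster` (realized areas, growing flags),
#'   `fields` (data.frame `field_id`, `owner`, `n_cells`) and `field_cells`
#'   (list of cell-index vectors, one per field).
#' @export
establish_all_fields <- function(grid, roster, config) {
  stopifnot(!any(is.na(roster$hb_x)))
  size_dist <- config$field_size_dist
  if (config$field_type == "percentage")
    size_dist <- dist_spec(size_dist$kind,
                           mean = config$field_size_percentage * config$hh_area_dist$mean,
                           sd = size_dist$sd)
  n_hh <- nrow(roster)
  hh_state <- lapply(seq_len(n_hh), function(i) list(
    id = roster$id[i], hb_x = roster$hb_x[i], hb_y = roster$hb_y[i],
    origin_x = roster$hb_x[i], origin_y = roster$hb_y[i],
    own_cells = integer(0), strategy_index = 1L, failed_tries = 0L))
  growing <- roster$growing
  realized <- roster$realized_cells
  expected <- roster$expected_cells
  area_target <- if (config$setup_type == "area")
    config$prop_agri_area * grid$width * grid$height else Inf
  total_field_cells <- sum(grid$landcover == LC_FIELD)
  fields <- list()
  field_cells <- list()
  next_field <- 1L

  while (any(growing) && total_field_cells < area_target) {
    order_ids <- sample(which(growing))
    for (hh in order_ids) {
      if (total_field_cells >= area_target) { growing[] <- FALSE; break }
      exhaust_count <- 0L
      repeat {
        f <- area_ha_to_cells(sample_sizes(size_dist, 1L), grid$cell_length_m)
        R <- realized[hh]; E <- expected[hh]
        if (!(R + f < E || abs(R + f - E) < abs(R - E))) {
          # a household with no field yet redraws (bounded below) rather than
          # retiring empty: every household establishes at least one field
          if (R > 0L) { growing[hh] <- FALSE; break }
          exhaust_count <- exhaust_count + 1L
          if (exhaust_count >= 3L) { growing[hh] <- FALSE; break }
          next
        }
        got <- FALSE
        repeat {
          res <- attempt_field_establishment(grid, hh_state[[hh]], f, config,
                                             next_field)
          hh_state[[hh]] <- res$household
          if (res$success) {
            fields[[next_field]] <- c(field_id = next_field,
                                      owner = roster$id[hh],
                                      n_cells = length(res$cells))
            field_cells[[next_field]] <- res$cells
            next_field <- next_field + 1L
            realized[hh] <- realized[hh] + length(res$cells)
            total_field_cells <- total_field_cells + length(res$cells)
            got <- TRUE
            break
          }
          if (res$exhausted) break
        }
        if (got) { exhaust_count <- 0L; break }
        exhaust_count <- exhaust_count + 1L
        if (exhaust_count >= 3L) { growing[hh] <- FALSE; break }
      }
    }
  }
  roster$realized_cells <- realized
  roster$growing <- growing
  fields_df <- if (length(fields))
    as.data.frame(do.call(rbind, fields)) else
    data.frame(field_id = integer(0), owner = integer(0), n_cells = integer(0))
  list(roster = roster, fields = fields_df, field_cells = field_cells)
}
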