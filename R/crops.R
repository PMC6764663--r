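# Crop type assignment: up to five crop types distributed over fields either
# by landscape-level area fractions alone, or additionally enforcing
# household-level specialization (the minimum fraction of households
# cultivating a crop that cultivate it exclusively).

#' Assign crop types to all established fields
#'
#' Target cell quotas per crop are `round(fraction_l x total field cells)`;
#' any shortfall from fractions summing to less than one goes to the fill-up
#' crop. Under `landscape-level-fraction`, fields are visited in seeded
#' random order and each is assigned the crop with the largest remaining
#' quota deficit, so fractions are met to within one field per crop. Under
#' `household-level-specialization` a first phase draws households in random
#' order and makes them specialists (all fields set to the crop) until the
#' specialist area reaches `specialization_l` of the crop quota; remaining
#' fields are filled against the remaining quotas as above; finally, while
#' the realized household-level specialization of a crop falls short of the
#' input level, randomly chosen mixed households cultivating that crop are
#' converted to specialists (realized levels can therefore exceed the input,
#' and quota overshoot is allowed and reported). Every field ends with
#' exactly one crop; fields are mono-crop units, so all cells of a field
#' share its crop.
#'
#' @param grid an `lgraf_grid` (crop layer mutated).
#' @param fields field table from [establish_all_fields()].
#' @param field_cells list of cell-index vectors per field.
#' @param config an [lgraf_config()] (crop table, fill-up crop, mode).
#' @return `fields` with a `crop` column (1-based crop id).
#' @export
assign_crops <- function(grid, fields, field_cells, config) {
  if (!nrow(fields)) { fields$crop <- integer(0); return(fields) }
  crops <- config$crops
  n_crops <- nrow(crops)
  total <- sum(fields$n_cells)
  quota <- round(crops$fraction * total)
  shortfall <- total - sum(quota)
  if (shortfall != 0)
    quota[config$fill_up_crop] <- quota[config$fill_up_crop] + shortfall
  assigned <- numeric(n_crops)
  crop_of <- rep(NA_integer_, nrow(fields))

  set_field <- function(fi, l) {
    crop_of[fi] <<- l
    assigned[l] <<- assigned[l] + fields$n_cells[fi]
  }

  if (config$land_use_assignment == "household-level-specialization") {
    owners <- unique(fields$owner)
    specialist_of <- rep(NA_integer_, length(owners))
    names(specialist_of) <- owners
    for (l in seq_len(n_crops)) {
      if (crops$specialization[l] <= 0 || quota[l] <= 0) next
      pool <- sample(owners[is.na(specialist_of[as.character(owners)])])
      for (hh in pool) {
        if (assigned[l] >= crops$specialization[l] * quota[l]) break
        specialist_of[as.character(hh)] <- l
        for (fi in which(fields$owner == hh)) set_field(fi, l)
      }
    }
  }

  open <- which(is.na(crop_of))
  for (fi in sample(open)) {
    l <- which.max(quota - assigned)
    set_field(fi, l)
  }

  if (config$land_use_assignment == "household-level-specialization") {
    tmp <- fields; tmp$crop <- crop_of
    for (l in seq_len(n_crops)) {
      if (crops$specialization[l] <= 0) next
      repeat {
        rs <- realized_specialization(tmp, l)
        if (is.na(rs) || rs >= crops$specialization[l] - 1e-12) break
        cult <- unique(tmp$owner[tmp$crop == l])
        mixed <- cult[vapply(cult, function(hh)
          any(tmp$crop[tmp$owner == hh] != l), logical(1))]
        if (!length(mixed)) break
        hh <- if (length(mixed) == 1L) mixed else sample(mixed, 1L)
        for (fi in which(tmp$owner == hh)) {
          assigned[tmp$crop[fi]] <- assigned[tmp$crop[fi]] - tmp$n_cells[fi]
          tmp$crop[fi] <- l
          assigned[l] <- assigned[l] + tmp$n_cells[fi]
        }
      }
      if (assigned[l] > quota[l])
        message(sprintf("crop %s: specialization overshoots quota (%d > %d cells)",
                        crops$name[l], assigned[l], quota[l]))
    }
    crop_of <- tmp$crop
  }

  for (fi in seq_along(field_cells))
    grid$crop[field_cells[[fi]]] <- crop_of[fi]
  fields$crop <- crop_of
  fields
}

#' Realized household-level specialization of a crop
#'
#' The fraction of households cultivating the crop whose every field is that
#' crop. `NA` (undefined) when no household cultivates the crop.
#'
#' @param fields field table with `owner` and `crop` columns.
#' @param crop_id 1-based crop id.
#' @return fraction in \[0, 1\], or `NA_real_` when undefined.
#' @export
realized_specialization <- function(fields, crop_id) {
  cult <- unique(fields$owner[fields$crop == crop_id])
  if (!length(cult)) return(NA_real_)
  pure <- vapply(cult, function(hh)
    all(fields$crop[fields$owner == hh] == crop_id), logical(1))
  sum(pure) / length(cult)
}
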