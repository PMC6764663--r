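# Full parameter set of the generator. Construction goes through
# lgraf_config() (canonical R names) or parse_config() (YAML document with
# the GUI key names); both end in validate_config().

# GUI key -> canonical name map used by parse_config(). Distribution triplets
# are assembled into dist_spec objects after mapping.
.gui_keys <- c(
  "setup-type"                    = "setup_type",
  "number-of-farmers"             = "n_households",
  "number-of-villages"            = "n_villages",
  "prop-agricultural-area"        = "prop_agri_area",
  "households-per-cell"           = "households_per_cell",
  "rnd-seed"                      = "seed",
  "reproducable?"                 = "reproducible",
  "width"                         = "width",
  "height"                        = "height",
  "cell-length-meter"             = "cell_length_m",
  "road-type"                     = "road_type",
  "road-map-file"                 = "road_file",
  "total-road-length"             = "total_road_length",
  "min-dist-roads"                = "min_dist_roads",
  "perlin-octaves"                = "perlin_octaves",
  "perlin-persistence"            = "perlin_persistence",
  "cone-angle"                    = "cone_angle",
  "dist-weight"                   = "dist_weight",
  "vlg-size-distribution"         = "vlg_size_kind",
  "vlg-size-mean_ha"              = "vlg_size_mean",
  "vlg-size-sd_ha"                = "vlg_size_sd",
  "vlg-min-distance"              = "vlg_min_distance",
  "hh-area-distribution"          = "hh_area_kind",
  "hh-area-mean_ha"               = "hh_area_mean",
  "hh-area-sd_ha"                 = "hh_area_sd",
  "inaccessible-area-fraction"    = "inacc_fraction",
  "inaccessible-area-location"    = "inacc_location",
  "inaccessible-area-distribution" = "inacc_kind",
  "inaccessible-area-mean"        = "inacc_mean",
  "inaccessible-area-sd"          = "inacc_sd",
  "field-type"                    = "field_type",
  "field-size-distribution"       = "field_size_kind",
  "field_size_mean_ha"            = "field_size_mean",
  "field_size_sd_ha"              = "field_size_sd",
  "field-size-percentage"         = "field_size_percentage",
  "field-shape-factor"            = "field_shape_factor",
  "strategies-type"               = "strategies_type",
  "s1.homebase"                   = "s1",
  "s2.fields"                     = "s2",
  "s3.nearby"                     = "s3",
  "s4.avoid"                      = "s4",
  "change-strategy"               = "change_strategy",
  "field-strategies-id"           = "field_strategies_id",
  "land-use-assignment"           = "land_use_assignment",
  "LUT-fill-up"                   = "fill_up_crop"
)

#' Build a generator configuration
#'
#' Assembles and validates the full parameter set of the landscape generator.
#' Every argument has a documented default except the quantity fixed by the
#' chosen `setup_type`: `"households"` requires `n_households`, `"villages"`
#' requires `n_villages`, and `"area"` requires `prop_agri_area` — the other
#' two quantities then emerge from the sampled household and village size
#' distributions.
#'
#' @param setup_type which quantity is fixed at initialization:
#'   `"households"`, `"villages"` or `"area"`.
#' @param n_households number of farming households (setup type `households`).
#' @param n_villages number of villages (setup type `villages`).
#' @param prop_agri_area target proportion of agricultural area in (0,1)
#'   (setup type `area`).
#' @param households_per_cell maximum number of household home-bases per cell.
#' @param seed random seed used when `reproducible` is `TRUE`.
#' @param reproducible if `TRUE` the run uses `seed`; otherwise a seed is
#'   drawn at generation time and recorded in the provenance output.
#' @param width,height landscape extent in cells.
#' @param cell_length_m side length of one cell in meters; one cell covers
#'   `(cell_length_m/100)^2` ha and should roughly match the smallest field.
#' @param road_type `"shapefile"` (vector file input, GeoJSON lines),
#'   `"artificial.perlin"` (noise-guided walker roads) or
#'   `"artificial.graffe"` (axis-aligned straight roads).
#' @param road_file path to a GeoJSON line layer (road type `shapefile`).
#' @param total_road_length target number of road cells (artificial roads).
#' @param min_dist_roads minimum distance in cells between two roads.
#' @param perlin_octaves,perlin_persistence fractal-noise parameters for the
#'   elevation field steering walker roads.
#' @param cone_angle forward search cone (degrees) of the road walker.
#' @param dist_weight weight in \[0,1\] of distance-to-target versus elevation
#'   in the walker's step score.
#' @param vlg_size_dist village size distribution ([dist_spec()], households).
#' @param vlg_min_distance minimum distance between village centers (cells).
#' @param hh_area_dist household area distribution ([dist_spec()], ha);
#'   restricted to `normal` / `log-normal`.
#' @param inacc_fraction fraction of the landscape covered by inaccessible
#'   area (large plantations / protected areas), in \[0,1).
#' @param inacc_location `"random"` or `"road-connected"` patch seeding.
#' @param inacc_dist inaccessible patch size distribution ([dist_spec()], ha).
#' @param field_type `"distribution"`: field sizes drawn from
#'   `field_size_dist`; `"percentage"`: the field size mean is set to
#'   `field_size_percentage` times the household area mean before sampling.
#' @param field_size_dist field size distribution ([dist_spec()], ha).
#' @param field_size_percentage multiplier in (0,1\] for field type
#'   `percentage`.
#' @param field_shape_factor >= 1; 1 gives compact, nearly square fields,
#'   larger values give narrow fields.
#' @param strategies ordered subset of `c("s1","s2","s3","s4")`: search close
#'   to the home-base (s1), close to own fields (s2), nearby others-cells
#'   with expanding radius (s3), others-cells fully surrounded by
#'   others-cells (s4).
#' @param change_strategy number of failed establishment tries after which a
#'   household switches to the next strategy in `strategies`.
#' @param land_use_assignment `"landscape-level-fraction"` or
#'   `"household-level-specialization"`.
#' @param crops data.frame with columns `name`, `fraction` and
#'   `specialization` (up to five rows). Fractions are shares of agricultural
#'   area and must sum to at most 1; specialization is the minimum fraction
#'   of households cultivating the crop that cultivate it exclusively.
#' @param fill_up_crop index (row of `crops`) receiving the remaining area
#'   when fractions sum to less than 1.
#' @return validated object of class `lgraf_config`.
#' @examples
#' cfg <- lgraf_config(setup_type = "area", prop_agri_area = 0.3)
#' @export
lgraf_config <- function(setup_type = c("area", "households", "villages"),
                         n_households = NULL,
                         n_villages = NULL,
                         prop_agri_area = NULL,
                         households_per_cell = 4L,
                         seed = 42L,
                         reproducible = TRUE,
                         width = 100L, height = 100L,
                         cell_length_m = 50,
                         road_type = c("artificial.graffe", "artificial.perlin", "shapefile"),
                         road_file = NULL,
                         total_road_length = 500L,
                         min_dist_roads = 10,
                         perlin_octaves = 4L,
                         perlin_persistence = 0.5,
                         cone_angle = 90,
                         dist_weight = 0.5,
                         vlg_size_dist = dist_spec("log-normal", 15, 5),
                         vlg_min_distance = 10,
                         hh_area_dist = dist_spec("log-normal", 2, 1),
                         inacc_fraction = 0,
                         inacc_location = c("random", "road-connected"),
                         inacc_dist = dist_spec("constant", 1),
                         field_type = c("distribution", "percentage"),
                         field_size_dist = dist_spec("log-normal", 1, 0.5),
                         field_size_percentage = 0.5,
                         field_shape_factor = 1,
                         strategies = c("s1", "s2", "s3", "s4"),
                         change_strategy = 3L,
                         land_use_assignment = c("landscape-level-fraction",
                                                 "household-level-specialization"),
                         crops = data.frame(name = "crop1", fraction = 1,
                                            specialization = 0),
                         fill_up_crop = 1L) {
  cfg <- list(
    setup_type = match.arg(setup_type),
    n_households = n_households,
    n_villages = n_villages,
    prop_agri_area = prop_agri_area,
    households_per_cell = as.integer(households_per_cell),
    seed = as.integer(seed),
    reproducible = isTRUE(reproducible),
    width = as.integer(width), height = as.integer(height),
    cell_length_m = as.numeric(cell_length_m),
    road_type = match.arg(road_type),
    road_file = road_file,
    total_road_length = as.integer(total_road_length),
    min_dist_roads = as.numeric(min_dist_roads),
    perlin_octaves = as.integer(perlin_octaves),
    perlin_persistence = as.numeric(perlin_persistence),
    cone_angle = as.numeric(cone_angle),
    dist_weight = as.numeric(dist_weight),
    vlg_size_dist = vlg_size_dist,
    vlg_min_distance = as.numeric(vlg_min_distance),
    hh_area_dist = hh_area_dist,
    inacc_fraction = as.numeric(inacc_fraction),
    inacc_location = match.arg(inacc_location),
    inacc_dist = inacc_dist,
    field_type = match.arg(field_type),
    field_size_dist = field_size_dist,
    field_size_percentage = as.numeric(field_size_percentage),
    field_shape_factor = as.numeric(field_shape_factor),
    strategies = strategies,
    change_strategy = as.integer(change_strategy),
    land_use_assignment = match.arg(land_use_assignment),
    crops = crops,
    fill_up_crop = as.integer(fill_up_crop)
  )
  class(cfg) <- "lgraf_config"
  validate_config(cfg)
}

#' Parse a YAML configuration document
#'
#' Reads the generator configuration from a YAML key/value document whose
#' keys follow the GUI parameter names (e.g. `setup-type`,
#' `prop-agricultural-area`, `hh-area-mean_ha`, `field-strategies-id`,
#' `LUT-1-name`, `LUT-1-fraction`, `LUT-1-specialize`, `LUT-fill-up`).
#' Unknown keys are rejected; defaults are applied only for keys with a
#' documented default (see [lgraf_config()]). Strategy selection follows
#' `strategies-type`: `manual` uses the boolean switches `s1.homebase` ..
#' `s4.avoid`; `id` uses the ordered list in `field-strategies-id` (e.g.
#' `"s1,s2,s4"`), which overrides the switches.
#'
#' @param source path to a YAML file, or a YAML string.
#' @return validated [lgraf_config()] object.
#' @export
parse_config <- function(source) {
  doc <- if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    yaml::read_yaml(source) else yaml::yaml.load(paste(source, collapse = "\n"))
  if (!is.list(doc)) stop("parse_config: document is not a key/value mapping",
                          call. = FALSE)
  lut_re <- "^LUT-([1-5])-(name|fraction|specialize)$"
  keys <- names(doc)
  known <- keys %in% names(.gui_keys) | grepl(lut_re, keys)
  if (any(!known))
    stop("parse_config: unknown key(s): ", paste(keys[!known], collapse = ", "),
         call. = FALSE)
  p <- stats::setNames(doc[keys %in% names(.gui_keys)],
                       .gui_keys[keys[keys %in% names(.gui_keys)]])

  args <- list()
  take <- function(name) if (!is.null(p[[name]])) p[[name]] else NULL
  for (nm in c("setup_type", "n_households", "n_villages", "prop_agri_area",
               "households_per_cell", "seed", "reproducible", "width", "height",
               "cell_length_m", "road_type", "road_file", "total_road_length",
               "min_dist_roads", "perlin_octaves", "perlin_persistence",
               "cone_angle", "dist_weight", "vlg_min_distance", "inacc_fraction",
               "inacc_location", "field_type", "field_size_percentage",
               "field_shape_factor", "change_strategy", "land_use_assignment",
               "fill_up_crop")) {
    v <- take(nm)
    if (!is.null(v)) args[[nm]] <- v
  }

  dist_from <- function(kind_key, mean_key, sd_key, default, allowed = NULL) {
    if (is.null(p[[kind_key]]) && is.null(p[[mean_key]]) && is.null(p[[sd_key]]))
      return(default)
    kind <- if (is.null(p[[kind_key]])) default$kind else p[[kind_key]]
    if (!is.null(allowed) && !kind %in% allowed)
      stop("parse_config: distribution kind '", kind, "' not allowed for ",
           kind_key, " (allowed: ", paste(allowed, collapse = ", "), ")",
           call. = FALSE)
    dist_spec(kind,
              mean = if (is.null(p[[mean_key]])) default$mean else p[[mean_key]],
              sd = if (is.null(p[[sd_key]])) default$sd else p[[sd_key]])
  }
  fmls <- formals(lgraf_config)
  args$vlg_size_dist <- dist_from("vlg_size_kind", "vlg_size_mean", "vlg_size_sd",
                                  eval(fmls$vlg_size_dist))
  args$hh_area_dist <- dist_from("hh_area_kind", "hh_area_mean", "hh_area_sd",
                                 eval(fmls$hh_area_dist),
                                 allowed = c("normal", "log-normal"))
  args$inacc_dist <- dist_from("inacc_kind", "inacc_mean", "inacc_sd",
                               eval(fmls$inacc_dist))
  args$field_size_dist <- dist_from("field_size_kind", "field_size_mean",
                                    "field_size_sd", eval(fmls$field_size_dist))

  # strategy resolution
  stype <- if (is.null(p$strategies_type)) "id" else p$strategies_type
  if (!stype %in% c("manual", "id"))
    stop("parse_config: strategies-type must be 'manual' or 'id'", call. = FALSE)
  if (stype == "id" && !is.null(p$field_strategies_id)) {
    ids <- p$field_strategies_id
    if (length(ids) == 1L) ids <- strsplit(ids, "[,; ]+")[[1]]
    args$strategies <- trimws(ids)
  } else if (stype == "manual") {
    flags <- vapply(c("s1", "s2", "s3", "s4"),
                    function(s) isTRUE(p[[s]]), logical(1))
    args$strategies <- c("s1", "s2", "s3", "s4")[flags]
  }

  # crop table from LUT-l-* keys
  lut <- keys[grepl(lut_re, keys)]
  if (length(lut)) {
    ls <- as.integer(sub(lut_re, "\\1", lut))
    fields <- sub(lut_re, "\\2", lut)
    n_crops <- max(ls)
    crops <- data.frame(name = paste0("crop", seq_len(n_crops)),
                        fraction = rep(0, n_crops),
                        specialization = rep(0, n_crops))
    for (i in seq_along(lut)) {
      val <- doc[[lut[i]]]
      crops[[c(name = "name", fraction = "fraction",
               specialize = "specialization")[fields[i]]]][ls[i]] <- val
    }
    args$crops <- crops
  }
  do.call(lgraf_config, args)
}

#' Validate a configuration
#'
#' Checks ranges, enum-dependent requirements and the crop fraction sum;
#' errors name the offending parameter. Called by [lgraf_config()]; exported
#' so externally assembled configurations can be re-checked.
#'
#' @param cfg an `lgraf_config` object.
#' @return `cfg`, invisibly unchanged, if valid.
#' @export
validate_config <- function(cfg) {
  fail <- function(...) stop("config: ", ..., call. = FALSE)
  pos_int <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1
  switch(cfg$setup_type,
    households = if (!pos_int(cfg$n_households))
      fail("setup-type 'households' requires a positive number-of-farmers"),
    villages = if (!pos_int(cfg$n_villages))
      fail("setup-type 'villages' requires a positive number-of-villages"),
    area = {
      if (is.null(cfg$prop_agri_area) || !is.numeric(cfg$prop_agri_area) ||
          cfg$prop_agri_area <= 0 || cfg$prop_agri_area >= 1)
        fail("setup-type 'area' requires prop-agricultural-area in (0, 1)")
    })
  if (!pos_int(cfg$width) || !pos_int(cfg$height))
    fail("width and height must be positive integers")
  if (cfg$cell_length_m <= 0) fail("cell-length-meter must be positive")
  if (!pos_int(cfg$households_per_cell)) fail("households-per-cell must be >= 1")
  if (cfg$road_type == "shapefile") {
    if (is.null(cfg$road_file)) fail("road-type 'shapefile' requires road-map-file")
  } else {
    if (cfg$total_road_length < 0) fail("total-road-length must be >= 0")
    if (cfg$total_road_length > 0.5 * cfg$width * cfg$height)
      fail("total-road-length exceeds half the landscape (", cfg$total_road_length, ")")
    if (cfg$min_dist_roads < 0) fail("min-dist-roads must be >= 0")
  }
  if (cfg$road_type == "artificial.perlin") {
    if (cfg$perlin_octaves < 1) fail("perlin-octaves must be >= 1")
    if (cfg$perlin_persistence <= 0 || cfg$perlin_persistence > 1)
      fail("perlin-persistence must be in (0, 1]")
    if (cfg$cone_angle <= 0 || cfg$cone_angle > 180)
      fail("cone-angle must be in (0, 180]")
    if (cfg$dist_weight < 0 || cfg$dist_weight > 1)
      fail("dist-weight must be in [0, 1]")
  }
  for (nm in c("vlg_size_dist", "hh_area_dist", "inacc_dist", "field_size_dist"))
    if (!inherits(cfg[[nm]], "lgraf_dist")) fail(nm, " is not a dist_spec")
  if (!cfg$hh_area_dist$kind %in% c("normal", "log-normal"))
    fail("hh-area-distribution must be normal or log-normal")
  if (cfg$vlg_min_distance < 0) fail("vlg-min-distance must be >= 0")
  if (cfg$inacc_fraction < 0 || cfg$inacc_fraction >= 1)
    fail("inaccessible-area-fraction must be in [0, 1)")
  if (cfg$field_type == "percentage" &&
      (cfg$field_size_percentage <= 0 || cfg$field_size_percentage > 1))
    fail("field-size-percentage must be in (0, 1]")
  if (cfg$field_shape_factor < 1)
    fail("field-shape-factor must be >= 1 (rectangular at 1, narrow above)")
  if (!length(cfg$strategies) || !all(cfg$strategies %in% c("s1", "s2", "s3", "s4")))
    fail("strategy list must be a non-empty subset of s1..s4 ",
         "(got: ", paste(cfg$strategies, collapse = ", "), ")")
  if (cfg$change_strategy < 1) fail("change-strategy must be >= 1")
  cr <- cfg$crops
  if (!is.data.frame(cr) || !all(c("name", "fraction", "specialization") %in% names(cr)) ||
      nrow(cr) < 1L || nrow(cr) > 5L)
    fail("crops must be a data.frame (1-5 rows) with name/fraction/specialization")
  if (any(cr$fraction < 0 | cr$fraction > 1) ||
      any(cr$specialization < 0 | cr$specialization > 1))
    fail("crop fractions and specializations must lie in [0, 1] (LUT-l-fraction)")
  s <- sum(cr$fraction)
  if (s > 1 + 1e-9) fail("fractions must sum up to 1 (LUT-l-fraction sum = ", s, ")")
  if (s < 1 - 1e-9) {
    if (is.null(cfg$fill_up_crop) || cfg$fill_up_crop < 1 ||
        cfg$fill_up_crop > nrow(cr))
      fail("LUT-fill-up must name a declared crop when fractions sum to < 1")
  }
  invisible(cfg)
}

#' @export
print.lgraf_config <- function(x, ...) {
  cat("<lgraf_config>\n")
  cat(sprintf("  grid: %d x %d cells of %g m (%g ha total)\n", x$width, x$height,
              x$cell_length_m, x$width * x$height * (x$cell_length_m / 100)^2))
  cat(sprintf("  setup-type: %s; roads: %s; strategies: %s\n", x$setup_type,
              x$road_type, paste(x$strategies, collapse = ",")))
  cat(sprintf("  crops: %s\n", paste(sprintf("%s(%.2f/%.2f)", x$crops$name,
              x$crops$fraction, x$crops$specialization), collapse = " ")))
  invisible(x)
}

# Deterministic per-stage seeds fanned out from one master seed so that one
# stage's draws never perturb another stage's stream.
stage_seed <- function(master, stage) {
  offs <- c(roads = 101L, roster = 211L, villages = 307L, homebases = 401L,
            inaccessible = 503L, fields = 601L, crops = 701L, fixture = 811L)
  if (!stage %in% names(offs)) stop("unknown rng stage: ", stage, call. = FALSE)
  as.integer((abs(as.numeric(master)) * 48271 + 7919 * offs[[stage]]) %% 2147483647)
}
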