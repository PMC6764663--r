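---
title: "Process-based generation of smallholder landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-based generation of smallholder landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgraf)
```

## The model

`lgraf` generates gridded land-use mosaics of agricultural landscapes shaped
by smallholder farming. Unlike neutral (pattern-based) landscape models,
which reproduce spatial statistics with abstract fractal parameters, the
generator simulates the *processes* believed to produce such mosaics:
households settle along roads, establish fields of empirically plausible
sizes close to their home-base, and specialize in crops. The parameters —
household area distributions, field size distributions, village sizes, crop
fractions — have direct empirical meaning and can be estimated from
household surveys or remote sensing.

A landscape is a regular lattice of square cells of side `cell_length_m`
meters (one cell covers `(cell_length_m/100)^2` ha). Every cell starts in
the aggregate class *others* (forest, grassland, water, degraded land).
The pipeline then runs:

1. **Roads** — polylines without spatial extent; a cell is a road cell iff a
   polyline intersects its closed square (supercover rasterization, so road
   lines are never broken by diagonal gaps). Roads come from a GeoJSON line
   file fitted affinely onto the grid extent, from a straight-road
   algorithm (axis-aligned full-span roads with alternating orientation and
   a minimum offset spacing), or from a noise-guided walker that crosses a
   fractal elevation field, trading off distance-to-target against terrain
   (`dist_weight`), constrained to a forward cone (`cone_angle`).
2. **Settlement** — the roster of households is built under one of three
   setup types, fixing either the household count, the village count, or
   the total agricultural proportion; the other two quantities emerge from
   the sampled household-area and village-size distributions. Village
   centers go on random road cells at a minimum spacing; each household
   takes the nearest road cell to its village center that still has
   home-base capacity.
3. **Inaccessible areas** (optional) — square-grown patches (company
   plantations, protected areas) that are closed to field establishment.
4. **Field establishment** — the core agent loop (below).
5. **Crop assignment** — landscape-level crop fractions, optionally with
   household-level specialization.
6. **Metrics and export** — class-level landscape metrics and seven raster
   map products.

## Field establishment

Each household has an expected area drawn at setup. In seeded random order,
still-growing households repeatedly draw a field size `f` from the
field-size distribution and compare the projected area `R + f` (realized
plus new field) with the expected area `E`: the field is attempted if
`R + f < E`, or if `|R + f - E| < |R - E|`; otherwise the household stops
growing. This realizes the configured household-area distribution up to the
granularity of single fields. A household that has drawn no field yet
redraws instead of retiring, so every household establishes at least one
field.

An attempt searches for a start cell using the current strategy:

* `s1` — nearest free others-cell to the home-base,
* `s2` — nearest free others-cell to any of the household's own fields,
* `s3` — expanding search from the most recent search origin,
* `s4` — like `s3`, but the cell and all its 8 neighbors must be free.

All searches expand ring by ring from the distance-1 ring outward, with
ties broken by a seeded shuffle; they are implemented as a global
nearest-cell argmin, which is equivalent to an expanding-radius search up
to the grid diagonal. After `change_strategy` failed tries the household
switches to the next strategy in its list; when the last strategy is
exhausted a fresh size is drawn, and three consecutive exhausted sizes
retire the household (the model itself does not bound redraws; the bound
guarantees termination). For `s3` the "most recent search origin" is the
last tried start cell — this makes `s3` genuinely different from `s1`,
which always re-anchors at the home-base.

Proposed fields are rectangles of width
`w = max(1, round(sqrt(size / shape_factor)))` and length `ceiling(size/w)`,
filled row-major to the exact size, with random orientation and four anchor
corners tried in turn. `shape_factor = 1` yields compact, nearly square
fields; larger values yield narrow strips. Fields may cover road cells and
the household's own home-base cell (road cells carry a land use like any
other cell); inaccessible cells are never eligible. No cell is ever owned
twice, and a household never expands into an existing field — its own or
anyone else's.

For setup-type `area` the loop additionally halts once total field cover
reaches the configured proportion. The halt is checked after every
established field rather than once per loop, so the overshoot is bounded by
a single field; combined with the roster being built to cover the target
minimally, the realized agricultural proportion lands within a fraction of
a percentage point of the configured value on average.

## Crop assignment and specialization

Quotas are `round(fraction_l x field cells)`, with the unallocated
remainder going to the fill-up crop. In fraction mode, fields are visited
in seeded random order and each takes the crop with the largest remaining
quota deficit — a greedy rule that meets fractions to within one field even
on small landscapes, where independent random draws would scatter widely.

Specialization is a *household-level* quantity: the minimum fraction of
households cultivating a crop that cultivate it exclusively. Because the
set of households cultivating a crop is only known once all fields are
assigned, the implementation proceeds in three steps: a seeding phase draws
households at random and converts them wholly to the crop until specialist
area reaches the specialization share of the crop quota; a filling phase
assigns the remaining fields greedily against the remaining quotas; and a
repair phase converts randomly chosen mixed households to specialists until
the realized level meets the input level. Realized specialization can
therefore exceed the input level — households with a single field are
specialists by construction — and the crop's cell quota may be overshot,
which is reported as a message.

## Landscape metrics

Five class-level metrics in the FRAGSTATS raster convention are computed on
any boolean class mask: number of patches, mean patch area (ha), largest
patch index (LPI, % of landscape cells in the largest patch), landscape
shape index (LSI, total class edge over the minimum edge of a maximally
compact arrangement of the same cell count) and patch cohesion index (PCI).
Patch identification uses queen (8-neighbor) adjacency by default, matching
the lineage of the tools these metrics come from; edge and perimeter
accounting always uses rook adjacency and includes the landscape boundary.
Both connectivities are exposed as a parameter so the choice is testable.
The habitat class ("others" patches) excludes road cells: roads function as
patch separators. Empty classes yield undefined (`NA`) metrics rather than
zeros, and PCI is undefined on a one-cell landscape.

## Numerical choices and defaults

* **Distributions.** All size distributions are parameterized by
  natural-scale mean and sd so the four shapes (constant, uniform, normal,
  log-normal) share one interface. The log-normal uses moment matching
  (`mu_log = log(mean^2/sqrt(sd^2+mean^2))`,
  `sigma_log = sqrt(log(1+sd^2/mean^2))`); the uniform is the
  moment-matched interval `mean ± sqrt(3) sd` (rejected if it crosses
  zero); normals are truncated below at a small positive floor (default
  0.01) by redraw, since areas must be positive. `sd = 0` always degenerates
  to the constant.
* **Hectares to cells.** Nearest integer with a floor of one cell. The cell
  size should be chosen close to the smallest field size of the system
  being emulated; the ±1-cell stopping granularity of the establishment
  rule biases realized areas low by a fraction of a cell per household, so
  household areas spanning many cells recover the configured mean closely
  (within 5% in the test conditions) while very coarse grids will not.
* **Geometry.** Cells are addressed `(x, y)`, 0-based, origin at the
  lower-left; the world is bounded (non-wrapping) — appropriate for
  comparing against cropped satellite samples.
* **Defaults** mirror the Indonesian smallholder system the generator was
  designed around: 100x100 cells of 50 m (2500 ha), log-normal household
  areas (2 ± 1 ha), log-normal field sizes (1 ± 0.5 ha), log-normal village
  sizes (15 ± 5 households), 500 road cells with a 10-cell minimum spacing,
  4 home-bases per cell, strategies `s1, s2, s3, s4` with a switch after 3
  failures. Survey medians reported for such systems (household areas of a
  few hectares, sub-hectare to hectare fields) motivate these magnitudes;
  all are plain configuration values.
* **Seeding.** One master seed fans out into fixed per-stage streams
  (roads, roster, villages, home-bases, inaccessible, fields, crops), so
  changing one stage's parameters never perturbs the draws of another, and
  a full run is byte-reproducible.

## What the synthetic conditions do and do not show

The test and acceptance conditions generate landscapes from the package's
own road and settlement processes, so they exercise the full pipeline
end-to-end but inherit its assumptions: homogeneous land suitability, no
temporal dynamics, identical strategy sets across households, dimensionless
roads. Passing them shows the generator realizes its configured
distributions, fractions and specialization levels and that the metrics
obey their definitional bounds — not that any particular real landscape is
reproduced. Matching real maps requires fitting parameters to survey or
remote-sensing data, which is exactly the intended use of the generator's
empirical parameterization.

Problem sizes in the bundled suites are chosen to make the full suite run
in minutes: definitional checks run on 100x100-cell landscapes (the size
used for the satellite-sample comparisons), while property sweeps
(Latin-hypercube metric bounds, the consolidation/specialization
regression) use 30x30 to 60x60 grids, which are large enough for dozens of
villages and hundreds of fields.

## Known limitations

* Vector road input is GeoJSON; ESRI Shapefile geometry is not parsed.
* The walker road generator is a reconstruction from the published
  parameter semantics (octaves, persistence, cone angle, distance weight);
  its exact scoring is defined by this package's documentation rather than
  an upstream reference.
* Strategy heterogeneity across households, temporal road growth, land
  suitability layers and spatial crop clustering controls are out of scope.

## A worked run

```{r example, eval = FALSE}
cfg <- lgraf_config(
  setup_type = "area", prop_agri_area = 0.3,
  crops = data.frame(name = c("oilpalm", "rubber"),
                     fraction = c(0.5, 0.5), specialization = c(0.7, 0)),
  land_use_assignment = "household-level-specialization")
res <- lgraf_generate(cfg, seed_override = 1)
res
realized_specialization(res$fields, 1)
subset(res$metrics, class == "fields")
run_generate(cfg, "landscape_out", seed_override = 1)
```
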