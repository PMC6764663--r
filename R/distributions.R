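#' Size distribution specification
#'
#' Household areas, village sizes, field sizes and inaccessible-area patch
#' sizes are all drawn from one of four distribution shapes. All shapes are
#' parameterized by their natural-scale mean and standard deviation so that a
#' single (mean, sd) interface covers every shape; the log-normal and uniform
#' parameters are obtained by moment matching.
#'
#' @param kind one of `"constant"`, `"uniform"`, `"normal"`, `"log-normal"`.
#' @param mean distribution mean on the natural scale (ha for areas,
#'   households for village sizes). Must be positive.
#' @param sd standard deviation, same units; must be non-negative. `sd = 0`
#'   behaves identically to `"constant"` for every kind.
#' @return an object of class `lgraf_dist`.
#' @examples
#' dist_spec("log-normal", mean = 2, sd = 1)
#' @export
dist_spec <- function(kind = c("constant", "uniform", "normal", "log-normal"),
                      mean, sd = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("dist_spec: 'mean' must be a single positive number", call. = FALSE)
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd < 0)
    stop("dist_spec: 'sd' must be a single non-negative number", call. = FALSE)
  if (kind == "uniform" && sd > 0 && mean - sqrt(3) * sd <= 0)
    stop("dist_spec: uniform lower bound mean - sqrt(3)*sd must be positive",
         call. = FALSE)
  structure(list(kind = kind, mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "lgraf_dist")
}

#' @export
print.lgraf_dist <- function(x, ...) {
  cat(sprintf("<size distribution: %s(mean = %g, sd = %g)>\n",
              x$kind, x$mean, x$sd))
  invisible(x)
}

#' Draw sizes from a distribution specification
#'
#' Draws `n` positive sizes. `constant` returns the mean exactly; `uniform`
#' draws on the moment-matched interval `[mean - sqrt(3) sd, mean + sqrt(3) sd]`;
#' `normal` is truncated below at `floor` by redraw (sizes must be positive);
#' `log-normal` uses natural-scale moment matching,
#' `mu_log = log(mean^2 / sqrt(sd^2 + mean^2))`,
#' `sigma_log = sqrt(log(1 + sd^2/mean^2))`.
#'
#' Draws consume the current R random number stream; seed with [set.seed()]
#' for reproducibility.
#'
#' @param dist an [dist_spec()] object.
#' @param n number of draws (>= 0).
#' @param floor positive truncation floor for the normal kind.
#' @return numeric vector of `n` positive sizes.
#' @export
sample_sizes <- function(dist, n, floor = 0.01) {
  stopifnot(inherits(dist, "lgraf_dist"), n >= 0)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))
  if (dist$sd == 0 || dist$kind == "constant") return(rep(dist$mean, n))
  switch(dist$kind,
    uniform = {
      half <- sqrt(3) * dist$sd
      if (dist$mean - half <= 0)
        stop("sample_sizes: uniform lower bound not positive", call. = FALSE)
      stats::runif(n, dist$mean - half, dist$mean + half)
    },
    normal = {
      if (floor <= 0) stop("sample_sizes: 'floor' must be positive", call. = FALSE)
      out <- stats::rnorm(n, dist$mean, dist$sd)
      bad <- which(out <= floor)
      while (length(bad)) {
        out[bad] <- stats::rnorm(length(bad), dist$mean, dist$sd)
        bad <- bad[out[bad] <= floor]
      }
      out
    },
    `log-normal` = {
      mu <- log(dist$mean^2 / sqrt(dist$sd^2 + dist$mean^2))
      sigma <- sqrt(log(1 + dist$sd^2 / dist$mean^2))
      stats::rlnorm(n, mu, sigma)
    })
}

#' Draw sizes until a target total is reached
#'
#' Patch sizes are drawn from the distribution until their running total
#' reaches `target_total`; the returned list is minimal in the sense that
#' dropping its last element would fall below the target.
#'
#' @inheritParams sample_sizes
#' @param target_total positive total to reach.
#' @return numeric vector whose sum is `>= target_total`.
#' @export
draw_until_total <- function(dist, target_total, floor = 0.01) {
  stopifnot(inherits(dist, "lgraf_dist"), target_total > 0)
  out <- numeric(0)
  total <- 0
  # batch draws; expected count ~ target/mean
  batch <- max(8L, ceiling(target_total / dist$mean))
  while (total < target_total) {
    draws <- sample_sizes(dist, batch, floor = floor)
    cs <- total + cumsum(draws)
    k <- which(cs >= target_total)
    if (length(k)) {
      out <- c(out, draws[seq_len(k[1L])])
      return(out)
    }
    out <- c(out, draws)
    total <- cs[batch]
    batch <- max(8L, ceiling((target_total - total) / dist$mean))
  }
  out
}

#' Convert an area in hectares to a whole number of grid cells
#'
#' One cell of side `cell_length_m` meters covers `(cell_length_m / 100)^2`
#' hectares. Areas are rounded to the nearest whole cell with a floor of one
#' cell, so every sampled household, field or patch occupies at least one cell.
#'
#' @param area_ha area in hectares (> 0).
#' @param cell_length_m cell side length in meters (> 0).
#' @return integer cell count >= 1 (vectorized over `area_ha`).
#' @examples
#' area_ha_to_cells(3.5, 50) # 14 cells of 0.25 ha
#' @export
area_ha_to_cells <- function(area_ha, cell_length_m) {
  if (any(area_ha <= 0) || cell_length_m <= 0)
    stop("area_ha_to_cells: areas and cell length must be positive", call. = FALSE)
  cell_ha <- (cell_length_m / 100)^2
  pmax(1L, as.integer(round(area_ha / cell_ha)))
}
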