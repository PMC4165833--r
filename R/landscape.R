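#' Generate a seeded synthetic farmland landscape
#'
#' Builds a coastal farmland mosaic of non-overlapping rectangular fields
#' arranged in east-west bands, with a "coast" roost polyline along the
#' southern edge of the extent and additional interior "lake" roost points.
#' Field areas are drawn from a truncated log-normal spanning
#' `area_range_ha`, crops are `"pasture"` with probability
#' `pasture_fraction` (the remainder split between new-sown cereal, stubble
#' and other crops), and historic goose use is a per-season binomial draw
#' whose success probability decays with roost distance. The same seed
#' always yields the identical landscape.
#'
#' @param n_fields number of fields (>= 2).
#' @param area_range_ha length-2 numeric, minimum and maximum field area in
#'   hectares.
#' @param pasture_fraction probability that a field is pasture, in (0, 1).
#' @param extent_m length-2 numeric, landscape width and height in metres.
#' @param n_roosts number of roosts (>= 1); the first is the coast
#'   polyline, the rest interior lakes.
#' @param historic_window_years length of the historic-use window in
#'   seasons.
#' @param seed integer seed; identical seeds give identical landscapes.
#' @return An object of class `landscape`: a list with `fields` (data frame
#'   with columns `id`, `xmin`, `xmax`, `ymin`, `ymax`, `cx`, `cy`,
#'   `area_ha`, `perimeter_m`, `crop`, `historic_use_years`), `roosts`
#'   (list of `list(id, kind, type, coords)`), `extent_m`, and `crs_note`.
#' @examples
#' ls <- generate_landscape(n_fields = 50, seed = 1)
#' nrow(ls$fields)
#' @export
generate_landscape <- function(n_fields = 1008,
                               area_range_ha = c(0.2, 14.41),
                               pasture_fraction = 0.26,
                               extent_m = c(20000, 20000),
                               n_roosts = 3,
                               historic_window_years = 4,
                               seed = 1) {
  if (n_fields < 2) {
    refugia_error("invalid_config", "n_fields must be at least 2")
  }
  if (length(area_range_ha) != 2 || any(area_range_ha <= 0) ||
    diff(area_range_ha) <= 0) {
    refugia_error("invalid_config", "area_range_ha must be positive and increasing")
  }
  if (pasture_fraction <= 0 || pasture_fraction >= 1) {
    refugia_error("invalid_config", "pasture_fraction must be in (0, 1)")
  }
  if (length(extent_m) != 2 || any(extent_m <= 0)) {
    refugia_error("invalid_config", "extent_m must be two positive lengths")
  }
  if (n_roosts < 1) {
    refugia_error("invalid_config", "need at least one roost")
  }
  if (historic_window_years < 0) {
    refugia_error("invalid_config", "historic_window_years must be >= 0")
  }

  with_seed(seed, {
    area_m2 <- draw_field_areas(n_fields, area_range_ha)
    fl <- place_field_bands(n_fields, area_m2, extent_m)
    fl$crop <- draw_crops(n_fields, pasture_fraction)
    roosts <- place_roosts(n_roosts, extent_m)

    d <- Reduce(pmin, lapply(
      roosts,
      function(r) points_geometry_distance(fl$cx, fl$cy, r)
    ))
    # Historic use: binomial over the window with occupancy probability
    # decaying on the same spatial scale geese commute from roosts.
    p_use <- 0.75 * exp(-d / 5000)
    fl$historic_use_years <- stats::rbinom(n_fields, historic_window_years, p_use)

    structure(
      list(
        fields = fl,
        roosts = roosts,
        extent_m = extent_m,
        historic_window_years = historic_window_years,
        crs_note = "planar metric coordinates (synthetic, no geographic CRS)"
      ),
      class = "landscape"
    )
  })
}

# Truncated log-normal field areas (m^2); resample draws falling outside the
# configured range so the seed fully determines the vector.
draw_field_areas <- function(n, area_range_ha) {
  lo <- area_range_ha[1] * 1e4
  hi <- area_range_ha[2] * 1e4
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog = log(2.0e4), sdlog = 0.85)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

draw_crops <- function(n, pasture_fraction) {
  rest <- 1 - pasture_fraction
  sample(
    c("pasture", "new_sown", "stubble", "other"),
    n,
    replace = TRUE,
    prob = c(pasture_fraction, rest * 0.5, rest * 0.3, rest * 0.2)
  )
}

# Fields laid out in horizontal bands from the coast inland. Gaps between
# neighbours are drawn from a mixture so that a realistic share of pairs sit
# close enough to count as adjoined refuge candidates.
place_field_bands <- function(n, area_m2, extent_m) {
  xmin <- xmax <- ymin <- ymax <- numeric(n)
  xcur <- stats::runif(1, 0, 60)
  ycur <- stats::runif(1, 10, 60)
  band_h <- stats::runif(1, 250, 400)
  for (i in seq_len(n)) {
    aspect <- stats::runif(1, 0.6, 1.8)
    h <- min(band_h, sqrt(area_m2[i] * aspect))
    w <- area_m2[i] / h
    if (xcur + w > extent_m[1]) {
      ycur <- ycur + band_h + stats::runif(1, 10, 60)
      band_h <- stats::runif(1, 250, 400)
      xcur <- stats::runif(1, 0, 60)
      h <- min(band_h, sqrt(area_m2[i] * aspect))
      w <- area_m2[i] / h
    }
    if (ycur + h > extent_m[2]) {
      refugia_error(
        "invalid_config",
        sprintf("extent %g x %g m too small for %d fields", extent_m[1], extent_m[2], n)
      )
    }
    xmin[i] <- xcur
    xmax[i] <- xcur + w
    ymin[i] <- ycur
    ymax[i] <- ycur + h
    gap <- if (stats::runif(1) < 0.35) stats::runif(1, 0, 15) else stats::runif(1, 30, 150)
    xcur <- xcur + w + gap
  }
  data.frame(
    id = sprintf("f%04d", seq_len(n)),
    xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
    cx = (xmin + xmax) / 2, cy = (ymin + ymax) / 2,
    area_ha = area_m2 * HA_PER_M2,
    perimeter_m = 2 * ((xmax - xmin) + (ymax - ymin)),
    crop = NA_character_,
    historic_use_years = NA_integer_,
    stringsAsFactors = FALSE
  )
}

place_roosts <- function(n_roosts, extent_m) {
  xs <- seq(0, extent_m[1], length.out = 8)
  coast <- list(
    id = "r01", kind = "coast", type = "polyline",
    coords = cbind(xs, stats::runif(8, 0, 40))
  )
  roosts <- list(coast)
  if (n_roosts > 1) {
    for (k in 2:n_roosts) {
      roosts[[k]] <- list(
        id = sprintf("r%02d", k), kind = "lake", type = "point",
        coords = cbind(
          stats::runif(1, 0.1, 0.9) * extent_m[1],
          stats::runif(1, 0.2, 0.9) * extent_m[2]
        )
      )
    }
  }
  roosts
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf(
    "<landscape> %d fields, %d roost(s), extent %.1f x %.1f km\n",
    nrow(x$fields), length(x$roosts),
    x$extent_m[1] / 1000, x$extent_m[2] / 1000
  ))
  cat(sprintf(
    "  field area: %.2f-%.2f ha (mean %.2f); pasture fraction %.2f\n",
    min(x$fields$area_ha), max(x$fields$area_ha), mean(x$fields$area_ha),
    mean(x$fields$crop == "pasture")
  ))
  invisible(x)
}

validate_landscape <- function(landscape) {
  if (!inherits(landscape, "landscape")) {
    refugia_error("invalid_landscape", "not a landscape object")
  }
  fl <- landscape$fields
  if (nrow(fl) < 2) refugia_error("invalid_landscape", "need at least 2 fields")
  if (anyDuplicated(fl$id)) refugia_error("invalid_landscape", "field ids must be unique")
  if (length(landscape$roosts) < 1) refugia_error("missing_roost", "need at least one roost")
  invisible(landscape)
}

#' Minimum roost distance of a field
#'
#' Distance in metres from a field's representative point (its centroid) to
#' the nearest roost geometry (point or polyline).
#'
#' @param field a single row of a landscape `fields` data frame (or any list
#'   with `cx`, `cy`).
#' @param roosts list of roost geometries as held in `landscape$roosts`.
#' @return distance in metres (>= 0).
#' @export
roost_distance <- function(field, roosts) {
  if (length(roosts) < 1) {
    refugia_error("missing_roost", "empty roost collection")
  }
  min(vapply(
    roosts,
    function(r) point_geometry_distance(field$cx, field$cy, r),
    numeric(1)
  ))
}

# Vectorised roost distance over all fields of a landscape.
roost_distances <- function(landscape) {
  fl <- landscape$fields
  Reduce(pmin, lapply(
    landscape$roosts,
    function(r) points_geometry_distance(fl$cx, fl$cy, r)
  ))
}
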