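#' Dropping-count survey design
#'
#' Three circles of radius 2 m per field: the first at the field centre,
#' the second two-thirds of the way from the edge to the centre, the third
#' one-third of the way from the edge. Control fields are drawn from the
#' pool of non-refuge fields within `control_pool_radius_m` of a refuge,
#' weighted by similarity in circumference to the refuges.
#'
#' @param circle_radius_m count-circle radius, metres.
#' @param circles_per_field circles per surveyed field (3 in the standard
#'   protocol).
#' @param control_pool_radius_m radius around refuges defining the
#'   control-candidate pool, metres.
#' @param seed integer seed for count noise and control sampling.
#' @param dispersion optional negative-binomial size parameter; `NULL`
#'   (default) keeps plain Poisson counts.
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(circle_radius_m = 2, circles_per_field = 3,
                          control_pool_radius_m = 2000, seed = 1,
                          dispersion = NULL) {
  if (circle_radius_m <= 0) refugia_error("invalid_config", "circle radius must be > 0")
  if (circles_per_field != 3) {
    refugia_error("invalid_config", "the protocol uses exactly 3 circles per field")
  }
  structure(
    list(
      circle_radius_m = circle_radius_m,
      circles_per_field = circles_per_field,
      control_pool_radius_m = control_pool_radius_m,
      seed = seed, dispersion = dispersion
    ),
    class = "survey_design"
  )
}

# Deterministic protocol circle centres for a rectangular field: field
# centre, then 2/3 and 1/3 of the edge-to-centre distance from the nearest
# boundary point, along the inward normal. Ties between equally near sides
# resolve in the fixed order left, right, bottom, top.
protocol_circle_centres <- function(field) {
  dists <- c(
    field$cx - field$xmin, field$xmax - field$cx,
    field$cy - field$ymin, field$ymax - field$cy
  )
  side <- which.min(dists)
  D <- dists[side]
  inward <- switch(side,
    c(1, 0),
    c(-1, 0),
    c(0, 1),
    c(0, -1)
  )
  edge_pt <- switch(side,
    c(field$xmin, field$cy),
    c(field$xmax, field$cy),
    c(field$cx, field$ymin),
    c(field$cx, field$ymax)
  )
  rbind(
    c(field$cx, field$cy),
    edge_pt + inward * (2 / 3) * D,
    edge_pt + inward * (1 / 3) * D
  )
}

#' Place the three protocol count circles in a field
#'
#' @param field one row of a landscape `fields` data frame.
#' @param design a [survey_design()].
#' @return 3 x 2 matrix of circle-centre coordinates (centre circle first).
#' @export
place_circles <- function(field, design) {
  inradius <- min(field$xmax - field$xmin, field$ymax - field$ymin) / 2
  if (inradius <= design$circle_radius_m) {
    refugia_error(
      "protocol_infeasible",
      sprintf("field %s too small to contain a %g m circle", field$id, design$circle_radius_m)
    )
  }
  protocol_circle_centres(field)
}

#' Draw dropping counts for one field's circles
#'
#' Counts are Poisson with mean equal to the local intensity at each circle
#' centre times the circle area (negative binomial with size
#' `design$dispersion` when overdispersion is switched on). The caller is
#' responsible for seeding; [run_survey()] seeds a whole survey
#' reproducibly.
#'
#' @param deposition a [simulate_deposition()] object.
#' @param field_id id of the surveyed field.
#' @param centres circle-centre matrix from [place_circles()].
#' @param design a [survey_design()].
#' @return integer vector of counts, one per circle.
#' @export
sample_counts <- function(deposition, field_id, centres, design) {
  lambda <- intensity_at(deposition, field_id, centres)
  if (any(lambda < 0)) refugia_error("model_integrity", "negative intensity")
  mu <- lambda * pi * design$circle_radius_m^2
  if (is.null(design$dispersion)) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), size = design$dispersion, mu = mu)
  }
}

#' Select stratified-random control fields
#'
#' Samples non-refuge fields without replacement from the pool of fields
#' whose centroids lie within `design$control_pool_radius_m` of any refuge
#' field, weighted by similarity in circumference to the refuges: a
#' candidate with perimeter P gets weight
#' `1 / (1 + |P - Pr| / max(P, Pr))` where Pr is the mean refuge
#' perimeter — a bounded, symmetric, scale-free similarity.
#'
#' @param refuges a `refuge_set`.
#' @param landscape the matching `landscape`.
#' @param design a [survey_design()]; its seed makes the draw reproducible.
#' @param n_controls number of control fields wanted.
#' @param seed override for the sampling seed (defaults to `design$seed`).
#' @return character vector of control field ids. If the pool is smaller
#'   than `n_controls` the whole pool is returned with a warning.
#' @export
select_controls <- function(refuges, landscape, design, n_controls,
                            seed = design$seed) {
  validate_landscape(landscape)
  fl <- landscape$fields
  ridx <- match(refuges$member_ids, fl$id)
  cand <- which(!(fl$id %in% refuges$member_ids))
  if (!length(cand)) refugia_error("empty_pool", "no non-refuge fields available")
  mind <- rep(Inf, length(cand))
  for (j in ridx) {
    mind <- pmin(mind, point_rect_distance(fl$cx[cand], fl$cy[cand], fl[j, ]))
  }
  pool <- cand[mind <= design$control_pool_radius_m]
  if (!length(pool)) refugia_error("empty_pool", "no candidates within the control radius")
  if (length(pool) <= n_controls) {
    if (length(pool) < n_controls) {
      refugia_warning(
        "small_pool",
        sprintf("pool (%d) smaller than n_controls (%d); returning whole pool", length(pool), n_controls)
      )
    }
    return(fl$id[pool])
  }
  p_ref <- mean(fl$perimeter_m[ridx])
  p <- fl$perimeter_m[pool]
  w <- 1 / (1 + abs(p - p_ref) / pmax(p, p_ref))
  with_seed(seed, fl$id[sample(pool, n_controls, prob = w)])
}

#' Run the dropping-count survey over refuges and controls
#'
#' Samples `n_refuge` of the refuge fields at random (all of them by
#' default), selects `n_controls` stratified-random control fields, places
#' the protocol circles in every surveyed field and draws seeded counts.
#' Distinct seeds are derived from `design$seed` for the refuge subsample,
#' the control draw and the count noise.
#'
#' @param landscape a `landscape`.
#' @param deposition the matching [simulate_deposition()] surface.
#' @param refuges a `refuge_set`.
#' @param design a [survey_design()].
#' @param n_refuge refuge fields to survey (`NULL` = all members).
#' @param n_controls control fields to survey.
#' @return a `survey_records` data frame: `field_id`, `is_refuge`, `crop`,
#'   `c1`, `c2`, `c3`, `mean_density_per_m2` where the density is the mean
#'   count divided by the circle area.
#' @export
run_survey <- function(landscape, deposition, refuges, design,
                       n_refuge = NULL, n_controls) {
  fl <- landscape$fields
  members <- refuges$member_ids
  surveyed_refuges <- if (is.null(n_refuge) || n_refuge >= length(members)) {
    members
  } else {
    with_seed(
      derive_seed(design$seed, "refuge-subsample"),
      sample(members, n_refuge)
    )
  }
  controls <- select_controls(refuges, landscape, design, n_controls,
    seed = derive_seed(design$seed, "control-selection")
  )
  ids <- c(surveyed_refuges, controls)
  counts <- with_seed(derive_seed(design$seed, "circle-counts"), {
    t(vapply(ids, function(id) {
      f <- fl[match(id, fl$id), ]
      sample_counts(deposition, id, place_circles(f, design), design)
    }, numeric(3)))
  })
  circle_area <- pi * design$circle_radius_m^2
  out <- data.frame(
    field_id = ids,
    is_refuge = ids %in% members,
    crop = fl$crop[match(ids, fl$id)],
    c1 = counts[, 1], c2 = counts[, 2], c3 = counts[, 3],
    mean_density_per_m2 = rowMeans(counts) / circle_area,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("survey_records", "data.frame")
  out
}
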