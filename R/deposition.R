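#' Goose dropping deposition model
#'
#' Parameterises the expected dropping-intensity surface. The field-centre
#' intensity of field *f* is
#' `base(f) * crop_multiplier[crop_f] * exp(-roost_distance(f) / decay_scale)`
#' where `base` is `lambda_refuge` on refuge fields and `lambda_far`
#' elsewhere. Within a field the intensity declines linearly from the centre
#' value to `edge_gradient` times the centre value at the boundary, matching
#' the expectation that geese use field centres most and edges least.
#'
#' @param lambda_refuge expected centre intensity (droppings per square
#'   metre) on an accommodated pasture at roost distance zero.
#' @param lambda_far baseline centre intensity on non-refuge pasture at
#'   roost distance zero.
#' @param decay_scale distance-decay scale in metres; `Inf` switches the
#'   roost-distance effect off.
#' @param edge_gradient fraction in `[0, 1]`: intensity at the field edge
#'   relative to the centre.
#' @param crop_multiplier named defecation-rate factors per crop; geese
#'   defecate more on grass than on grain, so pasture outranks stubble.
#' @param seed integer seed carried along for stochastic consumers.
#' @return an object of class `deposition_model`.
#' @export
deposition_model <- function(lambda_refuge = 3.56,
                             lambda_far = 0.27,
                             decay_scale = 5000,
                             edge_gradient = 0.5,
                             crop_multiplier = c(
                               pasture = 1, stubble = 0.5,
                               new_sown = 0.5, other = 0.1
                             ),
                             seed = 1) {
  if (lambda_refuge < 0 || lambda_far < 0) {
    refugia_error("invalid_config", "intensities must be >= 0")
  }
  if (edge_gradient < 0 || edge_gradient > 1) {
    refugia_error("invalid_config", "edge_gradient must lie in [0, 1]")
  }
  if (decay_scale <= 0) {
    refugia_error("invalid_config", "decay_scale must be > 0")
  }
  structure(
    list(
      lambda_refuge = lambda_refuge, lambda_far = lambda_far,
      decay_scale = decay_scale, edge_gradient = edge_gradient,
      crop_multiplier = crop_multiplier, seed = seed
    ),
    class = "deposition_model"
  )
}

#' Simulate the deposition intensity surface over a landscape
#'
#' Evaluates the deterministic expected-intensity surface of a
#' [deposition_model()] for every field, given which fields are refuges.
#' Count noise is added later, at survey time.
#'
#' @param landscape a `landscape` object.
#' @param refuge_ids character vector of refuge field ids (may be empty).
#' @param model a `deposition_model`.
#' @return an object of class `deposition`: the model plus a data frame
#'   `fields` with `id`, `is_refuge`, `roost_distance_m` and
#'   `centre_intensity` (droppings per square metre).
#' @export
simulate_deposition <- function(landscape, refuge_ids, model) {
  validate_landscape(landscape)
  fl <- landscape$fields
  unknown <- setdiff(refuge_ids, fl$id)
  if (length(unknown)) {
    refugia_error(
      "unknown_field",
      paste("unknown field id(s) in refuge_ids:", paste(unknown, collapse = ", "))
    )
  }
  mult <- model$crop_multiplier[fl$crop]
  if (anyNA(mult)) {
    refugia_error("invalid_config", "crop_multiplier missing a crop level")
  }
  d <- roost_distances(landscape)
  is_refuge <- fl$id %in% refuge_ids
  base <- ifelse(is_refuge, model$lambda_refuge, model$lambda_far)
  decay <- if (is.finite(model$decay_scale)) exp(-d / model$decay_scale) else 1
  structure(
    list(
      model = model,
      landscape = landscape,
      fields = data.frame(
        id = fl$id,
        is_refuge = is_refuge,
        roost_distance_m = d,
        centre_intensity = as.numeric(base * mult * decay),
        stringsAsFactors = FALSE
      )
    ),
    class = "deposition"
  )
}

#' @export
print.deposition <- function(x, ...) {
  cat(sprintf(
    "<deposition> %d fields (%d refuge); centre intensity %.3g-%.3g m^-2\n",
    nrow(x$fields), sum(x$fields$is_refuge),
    min(x$fields$centre_intensity), max(x$fields$centre_intensity)
  ))
  invisible(x)
}

#' Evaluate the intensity surface at points inside a field
#'
#' Linear decline from the centre value at the centroid to
#' `edge_gradient` times the centre value on the boundary, using relative
#' boundary depth as the interpolation coordinate.
#'
#' @param deposition a [simulate_deposition()] object.
#' @param field_id single field id.
#' @param points n x 2 matrix of coordinates inside the field.
#' @return numeric vector of intensities (droppings per square metre).
#' @export
intensity_at <- function(deposition, field_id, points) {
  i <- match(field_id, deposition$fields$id)
  if (is.na(i)) refugia_error("unknown_field", paste("unknown field id:", field_id))
  rect <- deposition$landscape$fields[i, ]
  centre <- deposition$fields$centre_intensity[i]
  eg <- deposition$model$edge_gradient
  depth <- rect_boundary_depth(points[, 1], points[, 2], rect)
  depth_c <- rect_boundary_depth(rect$cx, rect$cy, rect)
  rel <- pmin(1, pmax(0, depth / depth_c))
  centre * (eg + (1 - eg) * rel)
}

#' Protocol-defined true field density
#'
#' The noiseless dropping density a field would show under the three-circle
#' survey protocol: the mean of the intensity surface evaluated at the
#' three circle centres. This is the estimand the survey targets.
#'
#' @param deposition a [simulate_deposition()] object.
#' @param ids field ids (default: all fields).
#' @return named numeric vector of densities (droppings per square metre).
#' @export
field_density <- function(deposition, ids = deposition$fields$id) {
  out <- vapply(ids, function(id) {
    i <- match(id, deposition$landscape$fields$id)
    ctr <- protocol_circle_centres(deposition$landscape$fields[i, ])
    mean(intensity_at(deposition, id, ctr))
  }, numeric(1))
  names(out) <- ids
  out
}
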