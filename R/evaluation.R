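#' Compare refuge and control dropping densities
#'
#' Two-sided two-sample t test on dropping densities within one crop
#' stratum. The default is the pooled-variance Student form; Welch's
#' unequal-variance form is available behind the `test` flag.
#'
#' @param refuge_densities,control_densities numeric vectors of field mean
#'   densities (droppings per square metre), at least two per group.
#' @param crop_stratum label carried through to the result (e.g.
#'   `"pasture"` or `"stubble"`).
#' @param test `"student"` (pooled variance) or `"welch"`.
#' @return an object of class `comparison_result` with `t_statistic`,
#'   `df`, `p_value`, `group_means`, and `ratio` (refuge mean over control
#'   mean).
#' @export
compare_densities <- function(refuge_densities, control_densities,
                              crop_stratum = "pasture",
                              test = c("student", "welch")) {
  test <- match.arg(test)
  if (length(refuge_densities) < 2 || length(control_densities) < 2) {
    refugia_error("insufficient_data", "need >= 2 observations per group")
  }
  if ((length(refuge_densities) == 2 && stats::var(refuge_densities) == 0) ||
    (length(control_densities) == 2 && stats::var(control_densities) == 0)) {
    refugia_error("numeric_degeneracy", "a group of size 2 has zero variance")
  }
  ht <- stats::t.test(refuge_densities, control_densities,
    var.equal = (test == "student")
  )
  means <- c(refuge = mean(refuge_densities), control = mean(control_densities))
  structure(
    list(
      crop_stratum = crop_stratum,
      test = test,
      t_statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      group_means = means,
      ratio = unname(means["refuge"] / means["control"]),
      n = c(
        refuge = length(refuge_densities),
        control = length(control_densities)
      )
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s (%s t): t = %.2f, df = %.1f, p = %.3g\n  means %.3f vs %.3f m^-2 (ratio %.1f)\n",
    x$crop_stratum, x$test, x$t_statistic, x$df, x$p_value,
    x$group_means["refuge"], x$group_means["control"], x$ratio
  ))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Rho is Pearson's correlation of the average-rank transforms; the p
#' value uses the large-sample t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom
#' (two-sided).
#'
#' @param densities,covariate equal-length numeric vectors (n >= 3), e.g.
#'   dropping densities against roost distance or refuge size.
#' @return an object of class `correlation_result` with `rho`, `p_value`,
#'   `n`.
#' @export
spearman_cor <- function(densities, covariate) {
  if (length(densities) != length(covariate) || length(densities) < 3) {
    refugia_error("insufficient_data", "need equal-length vectors, n >= 3")
  }
  if (stats::var(densities) == 0 || stats::var(covariate) == 0) {
    refugia_error("undefined_correlation", "constant input vector")
  }
  rho <- stats::cor(rank(densities), rank(covariate))
  n <- length(densities)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> r_s = %.2f, p = %.3g, n = %d\n",
    x$rho, x$p_value, x$n
  ))
  invisible(x)
}

#' Cumulative priority-fractile coverage of refuge area
#'
#' Tallies refuge area per 5 % priority fractile and accumulates the
#' fraction of total refuge area reached by each fractile, in priority
#' order. Perfect adherence to the ranking puts all refuge area in the
#' first fractiles.
#'
#' @param refuges a `refuge_set`.
#' @param ranking the `priority_ranking` the refuges were drawn under.
#' @return a `coverage_curve` data frame: `fractile`, `refuge_area_ha`,
#'   `cumulative_fraction`.
#' @export
fractile_coverage <- function(refuges, ranking) {
  idx <- match(refuges$member_ids, ranking$id)
  if (anyNA(idx)) {
    refugia_error("inconsistent_inputs", "refuge member missing from ranking")
  }
  n_frac <- max(ranking$fractile_5)
  area <- refuges$ledger$area_ha[match(refuges$member_ids, refuges$ledger$id)]
  per <- vapply(
    seq_len(n_frac),
    function(k) sum(area[ranking$fractile_5[idx] == k]),
    numeric(1)
  )
  total <- sum(per)
  out <- data.frame(
    fractile = seq_len(n_frac),
    refuge_area_ha = per,
    cumulative_fraction = if (total > 0) cumsum(per) / total else rep(NA_real_, n_frac)
  )
  class(out) <- c("coverage_curve", "data.frame")
  out
}

#' Estimate the grazing-pressure share captured by refuges
#'
#' Multiplies grassland areas by dropping densities to obtain total
#' grazing pressures: grassland area is the suitable area times the grass
#' fraction; refuge and non-refuge pressures are their pasture areas times
#' their mean dropping densities; the captured share is the refuge
#' pressure over the total. Nothing is rounded in computation.
#'
#' @param suitable_area_km2 total area suitable for geese, square km.
#' @param grass_fraction fraction of farmland that is grassland.
#' @param refuge_pasture_km2 pasture area inside refuges, square km.
#' @param density_refuge,density_nonrefuge mean dropping densities
#'   (droppings per square metre) on refuge and non-refuge pasture.
#' @return an object of class `efficiency_report` with the area and
#'   pressure bookkeeping, `share_captured` and `area_share`.
#' @export
estimate_efficiency <- function(suitable_area_km2, grass_fraction,
                                refuge_pasture_km2, density_refuge,
                                density_nonrefuge) {
  if (density_refuge < 0 || density_nonrefuge < 0) {
    refugia_error("invalid_config", "densities must be >= 0")
  }
  grassland <- suitable_area_km2 * grass_fraction
  if (refuge_pasture_km2 > grassland) {
    refugia_error("infeasible_geometry", "refuge pasture exceeds grassland area")
  }
  nonrefuge <- grassland - refuge_pasture_km2
  pressure_refuge <- refuge_pasture_km2 * density_refuge
  pressure_nonrefuge <- nonrefuge * density_nonrefuge
  total <- pressure_refuge + pressure_nonrefuge
  structure(
    list(
      suitable_area_km2 = suitable_area_km2,
      grass_fraction = grass_fraction,
      grassland_area_km2 = grassland,
      refuge_pasture_km2 = refuge_pasture_km2,
      nonrefuge_pasture_km2 = nonrefuge,
      density_refuge = density_refuge,
      density_nonrefuge = density_nonrefuge,
      pressure_refuge = pressure_refuge,
      pressure_nonrefuge = pressure_nonrefuge,
      share_captured = if (total > 0) pressure_refuge / total else NA_real_,
      area_share = refuge_pasture_km2 / grassland
    ),
    class = "efficiency_report"
  )
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<efficiency_report>\n",
      "  grassland %.1f km^2 (refuge %.1f, non-refuge %.1f)\n",
      "  densities %.2f vs %.2f droppings m^-2\n",
      "  share captured %.1f %% on %.1f %% of the pasture area\n"
    ),
    x$grassland_area_km2, x$refuge_pasture_km2, x$nonrefuge_pasture_km2,
    x$density_refuge, x$density_nonrefuge,
    100 * x$share_captured, 100 * x$area_share
  ))
  invisible(x)
}

#' Merged refuge units with surveyed densities and roost distance
#'
#' Adjoined refuges are analysed as merged units: the grouped field area
#' is the refuge size and the unit density is the mean of the surveyed
#' densities of its member fields. Roost distance of a unit is the
#' area-weighted member centroid's distance to the nearest roost. Units
#' with no surveyed member are dropped.
#'
#' @param survey a [run_survey()] records table.
#' @param refuges a `refuge_set`.
#' @param landscape the `landscape`.
#' @return data frame `unit_id`, `area_ha`, `mean_density_per_m2`,
#'   `roost_distance_m`, `n_surveyed`.
#' @export
refuge_units <- function(survey, refuges, landscape) {
  fl <- landscape$fields
  memb <- refuges$units
  surveyed <- survey[survey$is_refuge, ]
  rows <- lapply(split(memb$id, memb$unit_id), function(ids) {
    dens <- surveyed$mean_density_per_m2[match(ids, surveyed$field_id)]
    dens <- dens[!is.na(dens)]
    if (!length(dens)) {
      return(NULL)
    }
    i <- match(ids, fl$id)
    w <- fl$area_ha[i]
    ctr <- c(sum(fl$cx[i] * w), sum(fl$cy[i] * w)) / sum(w)
    d <- min(vapply(
      landscape$roosts,
      function(r) point_geometry_distance(ctr[1], ctr[2], r),
      numeric(1)
    ))
    data.frame(
      unit_id = memb$unit_id[match(ids[1], memb$id)],
      area_ha = sum(fl$area_ha[i]),
      mean_density_per_m2 = mean(dens),
      roost_distance_m = d,
      n_surveyed = length(dens)
    )
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
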