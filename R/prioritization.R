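#' Compute the four suitability criteria for every field
#'
#' Per field: its size in hectares; connectivity, the summed area (ha) of
#' all other fields whose centroids lie within `neighbour_radius_m` of its
#' centroid; the recorded historic-use seasons; and the centroid distance
#' to the nearest roost.
#'
#' @param landscape a `landscape` object.
#' @param neighbour_radius_m neighbourhood radius for the connectivity
#'   criterion, metres.
#' @return a `criteria_table` data frame with columns `id`, `size_ha`,
#'   `connectivity_ha`, `historic_use_years`, `roost_distance_m`.
#' @export
compute_criteria <- function(landscape, neighbour_radius_m = 1000) {
  validate_landscape(landscape)
  fl <- landscape$fields
  d2 <- outer(fl$cx, fl$cx, `-`)^2 + outer(fl$cy, fl$cy, `-`)^2
  near <- d2 <= neighbour_radius_m^2
  diag(near) <- FALSE
  conn <- as.numeric(near %*% fl$area_ha)
  out <- data.frame(
    id = fl$id,
    size_ha = fl$area_ha,
    connectivity_ha = conn,
    historic_use_years = fl$historic_use_years,
    roost_distance_m = roost_distances(landscape),
    stringsAsFactors = FALSE
  )
  class(out) <- c("criteria_table", "data.frame")
  out
}

#' Rank fields by the four-criterion rank sum
#'
#' Each criterion is ranked with 1 = most suitable for geese: largest
#' size, largest connectivity, most seasons of historic use, smallest
#' roost distance. Ties take average ranks. The rank sum is the sum of the
#' four criterion ranks and the overall rank orders fields by ascending
#' rank sum; rank-sum ties are broken by smaller roost distance, then by
#' field id, so the ordering is deterministic.
#'
#' @param criteria a [compute_criteria()] table.
#' @return a `priority_ranking` data frame with the criteria, the four
#'   criterion ranks, `rank_sum`, `overall_rank`, and fractile labels
#'   `fractile_5` (1..20) and `fractile_20` (A..E).
#' @export
rank_fields <- function(criteria) {
  if (nrow(criteria) < 2) {
    refugia_error("incomplete_criteria", "ranking needs at least 2 fields")
  }
  need <- c("size_ha", "connectivity_ha", "historic_use_years", "roost_distance_m")
  if (anyNA(criteria[need])) {
    refugia_error("incomplete_criteria", "missing criterion value(s)")
  }
  out <- as.data.frame(criteria)
  out$rank_size <- rank(-out$size_ha, ties.method = "average")
  out$rank_connectivity <- rank(-out$connectivity_ha, ties.method = "average")
  out$rank_use <- rank(-out$historic_use_years, ties.method = "average")
  out$rank_distance <- rank(out$roost_distance_m, ties.method = "average")
  out$rank_sum <- out$rank_size + out$rank_connectivity +
    out$rank_use + out$rank_distance
  ord <- order(out$rank_sum, out$roost_distance_m, out$id)
  out$overall_rank <- integer(nrow(out))
  out$overall_rank[ord] <- seq_len(nrow(out))
  out$fractile_5 <- assign_fractiles(out, 0.05)
  out$fractile_20 <- LETTERS[assign_fractiles(out, 0.20)]
  class(out) <- c("priority_ranking", "data.frame")
  out
}

#' @export
print.priority_ranking <- function(x, ...) {
  cat(sprintf(
    "<priority_ranking> %d fields; rank sums %.1f-%.1f\n",
    nrow(x), min(x$rank_sum), max(x$rank_sum)
  ))
  utils::head(as.data.frame(x[order(x$overall_rank), c(
    "id", "rank_sum",
    "overall_rank", "fractile_5", "fractile_20"
  )]), 5) |> print(row.names = FALSE)
  invisible(x)
}

#' Partition ranked fields into priority fractiles
#'
#' Fields are taken in overall-rank order and cut into consecutive groups
#' of near-equal size (`ceiling(n * width)` or `floor(n * width)` fields;
#' any remainder goes to the earliest, highest-priority fractiles).
#' Fractile 1 is the highest-priority slice.
#'
#' @param ranking a `priority_ranking` (or any data frame with
#'   `overall_rank`).
#' @param width fractile width as a fraction, e.g. `0.05` or `0.20`.
#' @return integer fractile index per field, in the row order of `ranking`.
#' @export
assign_fractiles <- function(ranking, width) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0 || width >= 1) {
    refugia_error("invalid_width", "width must be a fraction in (0, 1)")
  }
  n <- nrow(ranking)
  g <- ceiling(1 / width - 1e-9)
  base <- n %/% g
  rem <- n %% g
  sizes <- rep(base, g) + c(rep(1L, rem), rep(0L, g - rem))
  idx <- rep(seq_len(g), sizes)
  idx[ranking$overall_rank]
}
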