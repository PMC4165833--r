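#' Subsidy scheme parameters
#'
#' @param budget total subsidy budget, NOK.
#' @param rate_pasture subsidy rate for pastures, NOK per hectare.
#' @param rate_new_sown subsidy rate for newly sown cereal fields (and for
#'   stubble fields destined for sowing), NOK per hectare.
#' @return an object of class `subsidy_scheme`.
#' @export
subsidy_scheme <- function(budget = 1.44e6, rate_pasture = 3000,
                           rate_new_sown = 1000) {
  if (budget <= 0 || rate_pasture <= 0 || rate_new_sown <= 0) {
    refugia_error("invalid_config", "budget and rates must be positive")
  }
  if (rate_pasture <= rate_new_sown) {
    refugia_error("invalid_config", "rate_pasture must exceed rate_new_sown")
  }
  structure(
    list(
      budget = budget, rate_pasture = rate_pasture,
      rate_new_sown = rate_new_sown
    ),
    class = "subsidy_scheme"
  )
}

# Per-field subsidy cost; NA marks ineligible crops. Stubble is costed at
# the new-sown rate because subsidised stubble fields are those destined to
# be turned into new-sown fields.
field_cost <- function(fields, scheme) {
  rate <- ifelse(
    fields$crop == "pasture", scheme$rate_pasture,
    ifelse(fields$crop %in% c("new_sown", "stubble"), scheme$rate_new_sown, NA_real_)
  )
  fields$area_ha * rate
}

#' Allocate the subsidy budget to refuge fields
#'
#' Greedy pass down the priority list: at each step, among the remaining
#' eligible fields whose cost fits the remaining budget, the candidate with
#' the lowest effective rank sum is selected, where a candidate adjacent
#' (boundary-to-boundary distance at most `adjacency_threshold_m`) to an
#' already-selected field has its rank sum reduced by `adjoin_bonus`. This
#' operationalises the authorities' practice of primarily following the
#' ranking while preferring to adjoin fields into larger refuge units.
#' Fields are subsidised whole or not at all; crops other than pasture,
#' new-sown and stubble are ineligible.
#'
#' @param ranking a [rank_fields()] table.
#' @param landscape the matching `landscape`.
#' @param scheme a [subsidy_scheme()].
#' @param adjoin_bonus rank-sum credit for adjoining an existing refuge
#'   (>= 0; 0 reproduces the pure priority list).
#' @param adjacency_threshold_m boundary distance, metres, under which two
#'   fields count as adjoined.
#' @return an object of class `refuge_set`: `member_ids`, `cost_total`,
#'   a per-field cost `ledger`, merged `units` (data frame `id`,
#'   `unit_id`) and `unit_areas` (data frame `unit_id`, `n_fields`,
#'   `area_ha`), plus the scheme and threshold used.
#' @export
allocate_refuges <- function(ranking, landscape, scheme, adjoin_bonus = 0,
                             adjacency_threshold_m = 20) {
  validate_landscape(landscape)
  if (adjoin_bonus < 0) refugia_error("invalid_config", "adjoin_bonus must be >= 0")
  fl <- landscape$fields
  if (!setequal(fl$id, ranking$id)) {
    refugia_error("inconsistent_inputs", "ranking and landscape field ids differ")
  }
  ord <- match(fl$id, ranking$id)
  rank_sum <- ranking$rank_sum[ord]
  overall <- ranking$overall_rank[ord]
  cost <- field_cost(fl, scheme)

  candidate <- which(!is.na(cost))
  selected <- integer(0)
  budget_left <- scheme$budget
  bounds <- fl[, c("xmin", "xmax", "ymin", "ymax")]
  adjacent <- rep(FALSE, nrow(fl))

  repeat {
    affordable <- candidate[cost[candidate] <= budget_left]
    if (!length(affordable)) break
    eff <- rank_sum[affordable] - adjoin_bonus * adjacent[affordable]
    pick <- affordable[order(eff, overall[affordable])[1]]
    selected <- c(selected, pick)
    budget_left <- budget_left - cost[pick]
    candidate <- setdiff(candidate, pick)
    if (adjoin_bonus > 0 && length(candidate)) {
      d <- rect_rect_distance(bounds[pick, ], bounds[candidate, ])
      adjacent[candidate][d <= adjacency_threshold_m] <- TRUE
    }
  }

  if (!length(selected)) {
    refugia_warning("empty_allocation", "budget below the cheapest eligible field")
  }
  member_ids <- fl$id[selected]
  units <- merge_adjacent(member_ids, landscape, adjacency_threshold_m)
  ledger <- data.frame(
    id = member_ids,
    crop = fl$crop[selected],
    area_ha = fl$area_ha[selected],
    rate_nok_ha = ifelse(fl$crop[selected] == "pasture",
      scheme$rate_pasture, scheme$rate_new_sown
    ),
    cost_nok = cost[selected],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      member_ids = member_ids,
      cost_total = sum(cost[selected]),
      ledger = ledger,
      units = units$membership,
      unit_areas = units$areas,
      scheme = scheme,
      adjacency_threshold_m = adjacency_threshold_m
    ),
    class = "refuge_set"
  )
}

#' @export
print.refuge_set <- function(x, ...) {
  cat(sprintf(
    "<refuge_set> %d fields in %d merged unit(s); %.1f ha; cost %.0f NOK (budget %.0f)\n",
    length(x$member_ids), nrow(x$unit_areas),
    sum(x$ledger$area_ha), x$cost_total, x$scheme$budget
  ))
  invisible(x)
}

#' Merge adjacent refuge fields into units
#'
#' Connected components of the graph joining member fields whose
#' boundary-to-boundary distance is at most `adjacency_threshold_m`.
#'
#' @param member_ids refuge member field ids.
#' @param landscape the `landscape` holding the fields.
#' @param adjacency_threshold_m boundary distance threshold, metres.
#' @return list with `membership` (data frame `id`, `unit_id`) and `areas`
#'   (data frame `unit_id`, `n_fields`, `area_ha`).
#' @export
merge_adjacent <- function(member_ids, landscape, adjacency_threshold_m = 20) {
  fl <- landscape$fields
  idx <- match(member_ids, fl$id)
  if (anyNA(idx)) {
    refugia_error("unknown_field", "member id not present in landscape")
  }
  n <- length(idx)
  if (n == 0) {
    return(list(
      membership = data.frame(id = character(0), unit_id = integer(0)),
      areas = data.frame(unit_id = integer(0), n_fields = integer(0), area_ha = numeric(0))
    ))
  }
  dm <- rect_distance_matrix(fl[idx, ])
  adj <- dm <= adjacency_threshold_m
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  membership <- data.frame(
    id = member_ids, unit_id = as.integer(comp),
    stringsAsFactors = FALSE
  )
  areas <- do.call(rbind, lapply(split(seq_len(n), comp), function(m) {
    data.frame(
      unit_id = comp[m[1]], n_fields = length(m),
      area_ha = sum(fl$area_ha[idx[m]])
    )
  }))
  rownames(areas) <- NULL
  list(membership = membership, areas = areas)
}
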