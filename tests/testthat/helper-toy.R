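# Hand-built landscapes with exactly known geometry, used wherever a test
# needs full control over field positions rather than the seeded generator.

# rects: data.frame with xmin, xmax, ymin, ymax and optionally crop /
# historic_use_years. roosts: list of list(kind, type, coords).
make_toy_landscape <- function(rects,
                               roosts = list(list(
                                 id = "r01", kind = "lake", type = "point",
                                 coords = matrix(c(0, 0), nrow = 1)
                               ))) {
  n <- nrow(rects)
  fields <- data.frame(
    id = rects$id %||% sprintf("f%04d", seq_len(n)),
    xmin = rects$xmin, xmax = rects$xmax,
    ymin = rects$ymin, ymax = rects$ymax,
    cx = (rects$xmin + rects$xmax) / 2,
    cy = (rects$ymin + rects$ymax) / 2,
    area_ha = (rects$xmax - rects$xmin) * (rects$ymax - rects$ymin) * 1e-4,
    perimeter_m = 2 * ((rects$xmax - rects$xmin) + (rects$ymax - rects$ymin)),
    crop = rects$crop %||% rep("pasture", n),
    historic_use_years = rects$historic_use_years %||% rep(0L, n),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      fields = fields, roosts = roosts,
      extent_m = c(max(rects$xmax), max(rects$ymax)),
      historic_window_years = 4,
      crs_note = "planar metric coordinates (toy)"
    ),
    class = "landscape"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Square fields of side `side` metres centred at (cx, cy).
square_fields <- function(cx, cy, side, ...) {
  data.frame(
    xmin = cx - side / 2, xmax = cx + side / 2,
    ymin = cy - side / 2, ymax = cy + side / 2,
    ...
  )
}

# A refuge_set wrapping the given member ids without running the budget
# allocation, for survey/evaluation tests that fix the refuges directly.
make_refuge_set <- function(member_ids, landscape, adjacency_threshold_m = 20) {
  units <- refugia::merge_adjacent(member_ids, landscape, adjacency_threshold_m)
  fl <- landscape$fields
  i <- match(member_ids, fl$id)
  structure(
    list(
      member_ids = member_ids,
      cost_total = 0,
      ledger = data.frame(
        id = member_ids, crop = fl$crop[i], area_ha = fl$area_ha[i],
        rate_nok_ha = 0, cost_nok = 0, stringsAsFactors = FALSE
      ),
      units = units$membership,
      unit_areas = units$areas,
      scheme = NULL,
      adjacency_threshold_m = adjacency_threshold_m
    ),
    class = "refuge_set"
  )
}
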