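# GeoJSON / CSV / YAML interchange. Fields travel as Polygon features with
# id/crop/area_ha/historic_use_years properties, roosts as Point or
# LineString features with a kind property.

#' Write a landscape to a GeoJSON FeatureCollection
#'
#' @param landscape a [generate_landscape()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path) {
  validate_landscape(landscape)
  fl <- landscape$fields
  feats <- lapply(seq_len(nrow(fl)), function(i) {
    ring <- rect_ring(fl[i, ])
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(j) ring[j, ]))
      ),
      properties = list(
        id = fl$id[i],
        crop = fl$crop[i],
        area_ha = fl$area_ha[i],
        historic_use_years = fl$historic_use_years[i]
      )
    )
  })
  rfeats <- lapply(landscape$roosts, function(r) {
    geom <- if (identical(r$type, "point")) {
      list(type = "Point", coordinates = as.numeric(r$coords[1, ]))
    } else {
      list(
        type = "LineString",
        coordinates = lapply(seq_len(nrow(r$coords)), function(j) r$coords[j, ])
      )
    }
    list(
      type = "Feature", geometry = geom,
      properties = list(id = r$id, kind = r$kind)
    )
  })
  fc <- list(
    type = "FeatureCollection",
    crs_note = landscape$crs_note,
    extent_m = landscape$extent_m,
    historic_window_years = landscape$historic_window_years,
    features = c(feats, rfeats)
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landscape from GeoJSON written by [write_landscape()]
#'
#' Field polygons are interpreted through their bounding rectangles (the
#' synthetic generator emits axis-aligned rectangles).
#'
#' @param path GeoJSON file path.
#' @return a `landscape` object.
#' @export
read_landscape <- function(path) {
  fc <- jsonlite::read_json(path)
  fields <- list()
  roosts <- list()
  for (ft in fc$features) {
    g <- ft$geometry
    if (identical(g$type, "Polygon")) {
      co <- do.call(rbind, lapply(g$coordinates[[1]], function(p) unlist(p)))
      fields[[length(fields) + 1L]] <- data.frame(
        id = ft$properties$id,
        xmin = min(co[, 1]), xmax = max(co[, 1]),
        ymin = min(co[, 2]), ymax = max(co[, 2]),
        cx = (min(co[, 1]) + max(co[, 1])) / 2,
        cy = (min(co[, 2]) + max(co[, 2])) / 2,
        area_ha = ft$properties$area_ha,
        perimeter_m = 2 * (diff(range(co[, 1])) + diff(range(co[, 2]))),
        crop = ft$properties$crop,
        historic_use_years = ft$properties$historic_use_years,
        stringsAsFactors = FALSE
      )
    } else {
      co <- if (identical(g$type, "Point")) {
        matrix(unlist(g$coordinates), nrow = 1)
      } else {
        do.call(rbind, lapply(g$coordinates, function(p) unlist(p)))
      }
      roosts[[length(roosts) + 1L]] <- list(
        id = ft$properties$id, kind = ft$properties$kind,
        type = if (identical(g$type, "Point")) "point" else "polyline",
        coords = co
      )
    }
  }
  structure(
    list(
      fields = do.call(rbind, fields),
      roosts = roosts,
      extent_m = unlist(fc$extent_m),
      historic_window_years = fc$historic_window_years %||% 4,
      crs_note = fc$crs_note %||% "planar metric coordinates"
    ),
    class = "landscape"
  )
}

#' Write a priority ranking table to CSV
#' @param ranking a [rank_fields()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.csv(as.data.frame(ranking), path, row.names = FALSE)
  invisible(path)
}

#' Read a priority ranking table written by [write_ranking()]
#' @param path CSV path.
#' @return a `priority_ranking` data frame.
#' @export
read_ranking <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("priority_ranking", "data.frame")
  df
}

#' Write a refuge set as GeoJSON plus a CSV cost ledger
#'
#' Member field polygons carry a `unit_id` property naming their merged
#' refuge unit; the ledger lists per-field subsidy costs.
#'
#' @param refuges an [allocate_refuges()] object.
#' @param landscape the landscape the refuges were drawn from.
#' @param geojson_path,ledger_path output paths.
#' @return `geojson_path`, invisibly.
#' @export
write_refuges <- function(refuges, landscape, geojson_path, ledger_path) {
  fl <- landscape$fields
  unit_of <- refuges$units$unit_id[match(refuges$member_ids, refuges$units$id)]
  feats <- lapply(seq_along(refuges$member_ids), function(k) {
    i <- match(refuges$member_ids[k], fl$id)
    ring <- rect_ring(fl[i, ])
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(j) ring[j, ]))
      ),
      properties = list(
        id = fl$id[i], crop = fl$crop[i], area_ha = fl$area_ha[i],
        unit_id = unit_of[k]
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats),
    geojson_path,
    auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(refuges$ledger, ledger_path, row.names = FALSE)
  invisible(geojson_path)
}

#' Write survey records to CSV
#' @param survey a survey-records data frame from [run_survey()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(survey, path, row.names = FALSE)
  invisible(path)
}
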