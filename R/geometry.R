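# Planar geometry primitives for axis-aligned rectangular fields and
# point/polyline roost features. All coordinates are planar metres; no
# geographic CRS handling happens in the core.

# Distance from point (px, py) to segment (ax, ay)-(bx, by); vectorised over
# segments.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(1, pmax(0, t))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Distance from a point to a roost geometry (list(kind, type, coords) with
# coords an n x 2 matrix; type "point" or "polyline").
point_geometry_distance <- function(px, py, geom) {
  min(points_geometry_distance(px, py, geom))
}

# Vectorised over many points against one geometry: per-point minimum
# distance to the geometry's vertices/segments.
points_geometry_distance <- function(px, py, geom) {
  co <- geom$coords
  if (nrow(co) == 1L || identical(geom$type, "point")) {
    d <- sqrt((px - co[1, 1])^2 + (py - co[1, 2])^2)
    if (nrow(co) > 1L) {
      for (k in 2:nrow(co)) {
        d <- pmin(d, sqrt((px - co[k, 1])^2 + (py - co[k, 2])^2))
      }
    }
    return(d)
  }
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(co) - 1L)) {
    d <- pmin(d, point_segment_distance(
      px, py,
      co[k, 1], co[k, 2], co[k + 1, 1], co[k + 1, 2]
    ))
  }
  d
}

# Boundary-to-boundary distance between two axis-aligned rectangles given as
# (xmin, xmax, ymin, ymax); 0 when they touch or overlap.
rect_rect_distance <- function(a, b) {
  dx <- pmax(0, pmax(b[["xmin"]] - a[["xmax"]], a[["xmin"]] - b[["xmax"]]))
  dy <- pmax(0, pmax(b[["ymin"]] - a[["ymax"]], a[["ymin"]] - b[["ymax"]]))
  sqrt(dx^2 + dy^2)
}

# Pairwise boundary distance matrix for the rectangle bounds held in a
# landscape fields table (vectorised; n kept small by callers).
rect_distance_matrix <- function(fl) {
  gx <- outer(fl$xmin, fl$xmax, `-`)
  dx <- pmax(gx, t(gx))
  dx[dx < 0] <- 0
  gy <- outer(fl$ymin, fl$ymax, `-`)
  dy <- pmax(gy, t(gy))
  dy[dy < 0] <- 0
  sqrt(dx^2 + dy^2)
}

# Distance from points to an axis-aligned rectangle (0 inside); vectorised
# over points.
point_rect_distance <- function(px, py, rect) {
  dx <- pmax(rect[["xmin"]] - px, 0, px - rect[["xmax"]])
  dy <- pmax(rect[["ymin"]] - py, 0, py - rect[["ymax"]])
  sqrt(dx^2 + dy^2)
}

# Signed distance from an interior point to the rectangle boundary
# (positive inside).
rect_boundary_depth <- function(px, py, rect) {
  pmin(
    px - rect[["xmin"]], rect[["xmax"]] - px,
    py - rect[["ymin"]], rect[["ymax"]] - py
  )
}

# Closed polygon ring (5 x 2) for a rectangle row of the fields table.
rect_ring <- function(rect) {
  cbind(
    c(rect[["xmin"]], rect[["xmax"]], rect[["xmax"]], rect[["xmin"]], rect[["xmin"]]),
    c(rect[["ymin"]], rect[["ymin"]], rect[["ymax"]], rect[["ymax"]], rect[["ymin"]])
  )
}
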