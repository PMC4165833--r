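# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and base rank()) so they can certify the implementation.

# Midranks by pairwise counting; larger values get rank 1 when
# decreasing = TRUE.
oracle_midrank <- function(x, decreasing = TRUE) {
  vapply(x, function(v) {
    better <- if (decreasing) sum(x > v) else sum(x < v)
    better + (sum(x == v) + 1) / 2
  }, numeric(1))
}

# Exhaustive sort-and-sum ranking: per-criterion midranks summed, overall
# order by rank sum, roost distance, then id.
oracle_rank_fields <- function(criteria) {
  rs <- oracle_midrank(criteria$size_ha) +
    oracle_midrank(criteria$connectivity_ha) +
    oracle_midrank(criteria$historic_use_years) +
    oracle_midrank(criteria$roost_distance_m, decreasing = FALSE)
  ord <- order(rs, criteria$roost_distance_m, criteria$id)
  overall <- integer(length(rs))
  overall[ord] <- seq_along(rs)
  list(rank_sum = rs, overall_rank = overall)
}

# Minimum field-to-roost distance by dense sampling of every roost
# geometry (polylines discretised to ~2000 points per segment chain).
oracle_roost_distance <- function(cx, cy, roosts) {
  min(vapply(roosts, function(r) {
    co <- r$coords
    pts <- if (nrow(co) == 1L || identical(r$type, "point")) {
      co
    } else {
      do.call(rbind, lapply(seq_len(nrow(co) - 1), function(k) {
        t <- seq(0, 1, length.out = 500)
        cbind(
          co[k, 1] + t * (co[k + 1, 1] - co[k, 1]),
          co[k, 2] + t * (co[k + 1, 2] - co[k, 2])
        )
      }))
    }
    min(sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2))
  }, numeric(1)))
}

# O(n^2) connectivity: summed area of other fields with centroids within
# the radius.
oracle_connectivity <- function(fields, radius) {
  n <- nrow(fields)
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) {
      if (j != i) {
        d <- sqrt((fields$cx[i] - fields$cx[j])^2 + (fields$cy[i] - fields$cy[j])^2)
        if (d <= radius) s <- s + fields$area_ha[j]
      }
    }
    s
  }, numeric(1))
}

# Textbook pooled-variance two-sample t test.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Boundary-to-boundary rectangle distance by dense boundary sampling.
oracle_rect_distance <- function(a, b, k = 200) {
  ring_pts <- function(r) {
    xs <- seq(r$xmin, r$xmax, length.out = k)
    ys <- seq(r$ymin, r$ymax, length.out = k)
    rbind(
      cbind(xs, r$ymin), cbind(xs, r$ymax),
      cbind(r$xmin, ys), cbind(r$xmax, ys)
    )
  }
  pa <- ring_pts(a)
  pb <- ring_pts(b)
  # overlap check: any corner strictly inside the other
  overlap <- a$xmin < b$xmax && b$xmin < a$xmax && a$ymin < b$ymax && b$ymin < a$ymax
  if (overlap) {
    return(0)
  }
  min(sqrt(outer(pa[, 1], pb[, 1], `-`)^2 + outer(pa[, 2], pb[, 2], `-`)^2))
}

# Connected components by boolean transitive closure of the adjacency
# matrix.
oracle_components <- function(adj) {
  m <- adj | diag(TRUE, nrow(adj))
  repeat {
    m2 <- (m %*% m) > 0
    if (identical(m2, m)) break
    m <- m2
  }
  comp <- integer(nrow(m))
  next_id <- 0L
  for (i in seq_len(nrow(m))) {
    if (comp[i] == 0L) {
      next_id <- next_id + 1L
      comp[m[i, ]] <- next_id
    }
  }
  comp
}

# Step-by-step re-simulation of the greedy budget pass, recomputing
# adjacency from scratch at every step.
oracle_greedy_allocation <- function(ranking, landscape, scheme, adjoin_bonus,
                                     threshold) {
  fl <- landscape$fields
  cost <- ifelse(
    fl$crop == "pasture", fl$area_ha * scheme$rate_pasture,
    ifelse(fl$crop %in% c("new_sown", "stubble"),
      fl$area_ha * scheme$rate_new_sown, NA
    )
  )
  rk <- ranking[match(fl$id, ranking$id), ]
  chosen <- character(0)
  left <- scheme$budget
  repeat {
    cand <- which(!is.na(cost) & !(fl$id %in% chosen) & cost <= left)
    if (!length(cand)) break
    eff <- vapply(cand, function(i) {
      adj <- FALSE
      for (id in chosen) {
        j <- match(id, fl$id)
        if (oracle_rect_distance(fl[i, ], fl[j, ]) <= threshold + 1e-9) adj <- TRUE
      }
      rk$rank_sum[i] - if (adj) adjoin_bonus else 0
    }, numeric(1))
    best <- cand[order(eff, rk$overall_rank[cand])][1]
    chosen <- c(chosen, fl$id[best])
    left <- left - cost[best]
  }
  chosen
}
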