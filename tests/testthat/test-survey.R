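test_that("circle placement follows the centre / two-thirds / one-third rule", {
  # square field, centre at origin, edge-to-centre distance D = 150
  ls <- make_toy_landscape(data.frame(
    xmin = c(-150, 500), xmax = c(150, 800),
    ymin = -150, ymax = c(150, -50)
  ))
  design <- survey_design(seed = 1)
  ctr <- place_circles(ls$fields[1, ], design)
  expect_equal(ctr[1, ], c(0, 0))
  d <- sqrt(rowSums(ctr^2))
  expect_equal(sort(d[2:3]), c(50, 100)) # D/3 and 2D/3 from the centre
  # deterministic: repeat call gives the identical placement
  expect_identical(ctr, place_circles(ls$fields[1, ], design))
})

test_that("all circle centres lie inside the field with margin >= radius", {
  design <- survey_design(seed = 2)
  set.seed(42)
  for (k in 1:50) {
    w <- runif(1, 30, 600)
    h <- runif(1, 30, 600)
    x0 <- runif(1, 0, 5000)
    y0 <- runif(1, 0, 5000)
    f <- make_toy_landscape(data.frame(
      xmin = c(x0, x0 + w + 1000), xmax = c(x0 + w, x0 + w + 1100),
      ymin = y0, ymax = c(y0 + h, y0 + 100)
    ))$fields[1, ]
    ctr <- place_circles(f, design)
    margin <- pmin(
      ctr[, 1] - f$xmin, f$xmax - ctr[, 1],
      ctr[, 2] - f$ymin, f$ymax - ctr[, 2]
    )
    expect_true(all(margin >= design$circle_radius_m))
  }
})

test_that("fields too small for the protocol are rejected by name", {
  ls <- make_toy_landscape(data.frame(
    xmin = c(0, 100), xmax = c(3, 200),
    ymin = 0, ymax = c(3, 100)
  ))
  err <- expect_error(
    place_circles(ls$fields[1, ], survey_design()),
    class = "refugia_protocol_infeasible"
  )
  expect_match(conditionMessage(err), "f0001")
})

test_that("counts are Poisson with mean intensity times circle area", {
  ls <- make_toy_landscape(square_fields(cx = c(500, 2000), cy = 500, side = 400))
  design <- survey_design(seed = 4)

  # zero intensity everywhere: all-zero counts and zero density
  dep0 <- simulate_deposition(
    ls, character(0),
    deposition_model(lambda_far = 0, lambda_refuge = 0)
  )
  ctr <- place_circles(ls$fields[1, ], design)
  expect_equal(sample_counts(dep0, "f0001", ctr, design), rep(0L, 3))

  # flat intensity 3.56: Monte-Carlo mean within 2 s.e. of 3.56 * pi * 4
  dep <- simulate_deposition(
    ls, "f0001",
    deposition_model(
      lambda_refuge = 3.56, decay_scale = Inf,
      edge_gradient = 1
    )
  )
  mu <- 3.56 * pi * design$circle_radius_m^2
  draws <- with(list(), {
    set.seed(99)
    replicate(3334, sample_counts(dep, "f0001", ctr, design))
  })
  expect_lt(abs(mean(draws) - mu), 2 * sqrt(mu / length(draws)))

  # an edge gradient below 1 depresses the expected count at the circle
  # nearest the edge relative to the centre circle
  dep2 <- simulate_deposition(
    ls, "f0001",
    deposition_model(decay_scale = Inf, edge_gradient = 0.3)
  )
  lam <- intensity_at(dep2, "f0001", ctr)
  expect_lt(lam[3], lam[1])
  expect_lt(lam[2], lam[1])
})

test_that("mean density is linear in counts and zero for empty records", {
  r <- 2
  circle_area <- pi * r^2
  counts <- c(5L, 11L, 2L)
  expect_equal(sum(counts) / (3 * circle_area), mean(counts) / circle_area)
  expect_equal(sum(c(0, 0, 0)) / (3 * circle_area), 0)
})

test_that("control selection excludes refuges and respects the pool radius", {
  ls <- generate_landscape(n_fields = 300, seed = 31)
  rk <- rank_fields(compute_criteria(ls, 1000))
  ref <- allocate_refuges(rk, ls, subsidy_scheme(budget = 3e5))
  design <- survey_design(seed = 7)
  ids <- select_controls(ref, ls, design, n_controls = 40)
  expect_length(ids, 40)
  expect_length(intersect(ids, ref$member_ids), 0)
  fl <- ls$fields
  ridx <- match(ref$member_ids, fl$id)
  for (id in ids) {
    i <- match(id, fl$id)
    dmin <- min(vapply(ridx, function(j) {
      dx <- max(fl$xmin[j] - fl$cx[i], 0, fl$cx[i] - fl$xmax[j])
      dy <- max(fl$ymin[j] - fl$cy[i], 0, fl$cy[i] - fl$ymax[j])
      sqrt(dx^2 + dy^2)
    }, numeric(1)))
    expect_lte(dmin, design$control_pool_radius_m)
  }
  # reproducible under the same design seed
  expect_identical(ids, select_controls(ref, ls, design, n_controls = 40))
})

test_that("identical perimeters give uniform control inclusion", {
  rects <- square_fields(cx = seq(100, 2100, by = 250), cy = 100, side = 100)
  ls <- make_toy_landscape(rects)
  ref <- make_refuge_set("f0001", ls)
  pool_n <- nrow(rects) - 1
  reps <- 3000
  freq <- table(unlist(lapply(seq_len(reps), function(s) {
    select_controls(ref, ls, survey_design(control_pool_radius_m = 1e5), 3, seed = s)
  })))
  p <- 3 / pool_n
  expect_true(all(abs(freq / reps - p) < 4 * sqrt(p * (1 - p) / reps)))
})

test_that("perimeter similarity weights drive inclusion odds", {
  # candidate at the refuge perimeter (weight 1) vs one with double the
  # perimeter (weight 2/3): single-control draws should split 0.6 / 0.4
  rects <- data.frame(
    xmin = c(0, 300, 700), xmax = c(100, 400, 900),
    ymin = 0, ymax = c(100, 100, 200)
  )
  ls <- make_toy_landscape(rects)
  ref <- make_refuge_set("f0001", ls) # perimeter 400
  design <- survey_design(control_pool_radius_m = 1e5)
  picks <- vapply(
    seq_len(4000),
    function(s) select_controls(ref, ls, design, 1, seed = s),
    character(1)
  )
  p_same <- mean(picks == "f0002")
  expect_lt(abs(p_same - 0.6), 4 * sqrt(0.6 * 0.4 / 4000))
})

test_that("a flat surface induces no refuge-control design bias", {
  ls <- generate_landscape(n_fields = 120, seed = 55)
  rk <- rank_fields(compute_criteria(ls, 1000))
  ref <- allocate_refuges(rk, ls, subsidy_scheme(budget = 2e5))
  dep <- simulate_deposition(
    ls, ref$member_ids,
    deposition_model(
      lambda_refuge = 1.2, lambda_far = 1.2, decay_scale = Inf,
      edge_gradient = 1,
      crop_multiplier = c(pasture = 1, stubble = 1, new_sown = 1, other = 1)
    )
  )
  diffs <- vapply(1:200, function(s) {
    sv <- run_survey(ls, dep, ref, survey_design(seed = s), n_controls = 20)
    mean(sv$mean_density_per_m2[sv$is_refuge]) -
      mean(sv$mean_density_per_m2[!sv$is_refuge])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * sd(diffs) / sqrt(length(diffs)))
})
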