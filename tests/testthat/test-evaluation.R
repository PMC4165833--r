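test_that("identical groups give t = 0, p = 1, ratio = 1", {
  x <- c(0.5, 1.0, 1.5, 2.0)
  res <- compare_densities(x, x)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$ratio, 1)
})

test_that("the printed refuge/control means give a 13-fold ratio", {
  res <- compare_densities(c(3.46, 3.66), c(0.17, 0.37))
  expect_equal(res$ratio, 3.56 / 0.27)
  expect_equal(round(res$ratio), 13)
})

test_that("t statistics match the textbook pooled-variance oracle", {
  set.seed(314)
  for (k in 1:20) {
    x <- rexp(sample(3:30, 1), rate = 1 / 2)
    y <- rexp(sample(3:30, 1), rate = 1)
    res <- compare_densities(x, y)
    o <- oracle_pooled_t(x, y)
    expect_equal(res$t_statistic, o$t)
    expect_equal(res$df, o$df)
    expect_equal(res$p_value, o$p)
  }
  # Welch flag: degrees of freedom drop below the pooled value under
  # unequal variances and the statistic matches stats::t.test
  x <- c(1, 4, 9, 2, 8, 3)
  y <- c(0.1, 0.2, 0.15, 0.12)
  res_w <- compare_densities(x, y, test = "welch")
  ht <- t.test(x, y)
  expect_equal(res_w$t_statistic, unname(ht$statistic))
  expect_equal(res_w$df, unname(ht$parameter))
})

test_that("degenerate groups are rejected", {
  expect_error(compare_densities(c(1), c(1, 2)), class = "refugia_insufficient_data")
  expect_error(compare_densities(c(1, 1), c(1, 2)), class = "refugia_numeric_degeneracy")
})

test_that("spearman_cor matches hand ranks and the antitone limit", {
  x <- c(5, 4, 3, 2, 1)
  expect_equal(spearman_cor(x, 1:5)$rho, -1)
  # five hand-listed pairs; ranks of x: (2,5,3,1,4), ranks of y: (1,4,5,2,3)
  x <- c(1.2, 9.0, 2.5, 0.3, 4.4)
  y <- c(10, 40, 50, 20, 30)
  d <- c(2 - 1, 5 - 4, 3 - 5, 1 - 2, 4 - 3)
  rho_hand <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
  res <- spearman_cor(x, y)
  expect_equal(res$rho, rho_hand)
  expect_equal(res$n, 5)
  # agreement with the standard implementation on tied data
  xt <- c(1, 2, 2, 3, 5, 5, 7)
  yt <- c(3, 1, 4, 4, 6, 8, 9)
  expect_equal(spearman_cor(xt, yt)$rho, cor(xt, yt, method = "spearman"))
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "refugia_undefined_correlation")
  expect_error(spearman_cor(1:2, 1:2), class = "refugia_insufficient_data")
})

test_that("fractile coverage is monotone with the right limits", {
  ls <- generate_landscape(n_fields = 200, seed = 41)
  rk <- rank_fields(compute_criteria(ls, 1000))

  # perfect adherence: refuges exactly the top 5 % of fields
  top <- rk$id[rk$overall_rank <= 10]
  cov_top <- fractile_coverage(make_refuge_set(top, ls), rk)
  expect_equal(cov_top$cumulative_fraction[1], 1)
  expect_true(all(cov_top$cumulative_fraction == 1))

  # uniform null: one refuge per fractile of equal-area fields tracks the
  # diagonal
  per_fractile <- vapply(
    1:20,
    function(k) rk$id[rk$fractile_5 == k][1],
    character(1)
  )
  ref_u <- make_refuge_set(per_fractile, ls)
  cov_u <- fractile_coverage(ref_u, rk)
  areas <- ls$fields$area_ha[match(per_fractile, ls$fields$id)]
  expect_equal(cov_u$cumulative_fraction, cumsum(areas) / sum(areas))

  # general invariants on an allocated refuge set
  ref <- allocate_refuges(rk, ls, subsidy_scheme(budget = 3e5))
  cov <- fractile_coverage(ref, rk)
  expect_true(all(diff(cov$cumulative_fraction) >= -1e-12))
  expect_equal(cov$cumulative_fraction[nrow(cov)], 1)

  bad <- ref
  bad$member_ids <- c(bad$member_ids, "ghost")
  bad$ledger <- rbind(bad$ledger, data.frame(
    id = "ghost", crop = "pasture",
    area_ha = 1, rate_nok_ha = 0, cost_nok = 0
  ))
  expect_error(fractile_coverage(bad, rk), class = "refugia_inconsistent_inputs")
})

test_that("greedy top-k allocations concentrate all area in top fractiles", {
  rects <- square_fields(cx = seq(100, 9700, length.out = 40), cy = 100, side = 120)
  rects$crop <- "pasture"
  rects$historic_use_years <- rep(0:3, 10)
  ls <- make_toy_landscape(rects)
  rk <- rank_fields(compute_criteria(ls, 500))
  k <- 6
  cost <- 1.44 * 3000
  ref <- allocate_refuges(rk, ls, subsidy_scheme(budget = k * cost + 1), adjoin_bonus = 0)
  cov <- fractile_coverage(ref, rk)
  top_fractiles <- unique(rk$fractile_5[rk$overall_rank <= k])
  expect_equal(cov$cumulative_fraction[max(top_fractiles)], 1)
})

test_that("the efficiency bookkeeping reproduces its identities", {
  rep_ <- estimate_efficiency(104, 0.26, 3.6, 3.56, 0.27)
  expect_equal(rep_$grassland_area_km2, 27.04)
  expect_equal(rep_$nonrefuge_pasture_km2, 23.44)
  expect_equal(
    rep_$share_captured,
    (3.6 * 3.56) / (3.6 * 3.56 + 23.44 * 0.27)
  )
  expect_equal(rep_$area_share, 3.6 / 27.04)

  # equal densities: the captured share collapses to the area share
  eq <- estimate_efficiency(104, 0.26, 3.6, 1.1, 1.1)
  expect_equal(eq$share_captured, eq$area_share)

  # no background pressure: refuges capture everything
  one <- estimate_efficiency(104, 0.26, 3.6, 2.0, 0)
  expect_equal(one$share_captured, 1)

  expect_error(
    estimate_efficiency(10, 0.26, 5, 1, 1),
    class = "refugia_infeasible_geometry"
  )
  expect_error(
    estimate_efficiency(10, 0.26, 1, -1, 1),
    class = "refugia_invalid_config"
  )
})

test_that("the captured share is monotone in the density contrast", {
  base <- estimate_efficiency(104, 0.26, 3.6, 3.56, 0.27)$share_captured
  up <- estimate_efficiency(104, 0.26, 3.6, 4.56, 0.27)$share_captured
  down <- estimate_efficiency(104, 0.26, 3.6, 3.56, 0.40)$share_captured
  expect_gt(up, base)
  expect_lt(down, base)
})

test_that("pressure totals equal area times area-weighted mean density", {
  r <- estimate_efficiency(104, 0.26, 3.6, 3.56, 0.27)
  wmean <- (r$refuge_pasture_km2 * r$density_refuge +
    r$nonrefuge_pasture_km2 * r$density_nonrefuge) / r$grassland_area_km2
  expect_equal(r$pressure_refuge + r$pressure_nonrefuge, r$grassland_area_km2 * wmean)
})

test_that("merged units average member densities and use grouped areas", {
  rects <- square_fields(cx = c(100, 210, 1000, 3000), cy = 100, side = 100)
  ls <- make_toy_landscape(rects)
  ref <- make_refuge_set(ls$fields$id[1:3], ls, adjacency_threshold_m = 20)
  expect_equal(nrow(ref$unit_areas), 2) # fields 1+2 adjoin (10 m gap)
  survey <- data.frame(
    field_id = ls$fields$id[1:3],
    is_refuge = TRUE,
    crop = "pasture",
    c1 = 0L, c2 = 0L, c3 = 0L,
    mean_density_per_m2 = c(2, 4, 1)
  )
  units <- refuge_units(survey, ref, ls)
  expect_equal(sort(units$mean_density_per_m2), c(1, 3))
  expect_equal(sort(units$area_ha), c(1, 2))
})
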