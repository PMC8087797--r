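test_that("deterministic Horton tree has the enumerated shape and lengths", {
  hp <- horton_params(r_b = 2, r_l = 2, mean_l1 = 1.3, max_order = 3,
                      length_cv = 0)
  net <- generate_network(hp, seed = 1)
  top <- network_topology(net)
  counts <- table(top$strahler_order)
  expect_equal(as.integer(counts[c("1", "2", "3")]), c(4L, 2L, 1L))
  lens <- vapply(net$segments, function(s) polyline_length(s$coords), numeric(1))
  by_order <- tapply(lens, top$strahler_order, mean)
  expect_equal(as.numeric(by_order), c(1.3, 2.6, 5.2), tolerance = 1e-9)
  expect_equal(net$total_length_km, 4 * 1.3 + 2 * 2.6 + 5.2, tolerance = 1e-9)
})

test_that("max_order = 1 yields a single segment of length mean_l1", {
  net <- generate_network(horton_params(max_order = 1, mean_l1 = 2.5,
                                        length_cv = 0), seed = 3)
  expect_length(net$segments, 1)
  expect_equal(polyline_length(net$segments[[1]]$coords), 2.5, tolerance = 1e-9)
})

test_that("infeasible regions fail loudly instead of clipping", {
  hp <- horton_params(max_order = 4, mean_l1 = 5, length_cv = 0)
  expect_error(generate_network(hp, region = c(-1, 1, 0, 2), seed = 1),
               "infeasible embedding")
})

test_that("assigned Strahler orders equal recomputed orders (consistency)", {
  for (s in 1:8) {
    hp <- horton_params(r_b = 2, r_l = 2, mean_l1 = 1,
                        max_order = sample(2:5, 1), length_cv = 0.25)
    net <- generate_network(hp, seed = s)
    top <- network_topology(net)
    rec <- strahler_orders(top[, c("segment_id", "parent_id")])
    expect_equal(unname(rec[top$segment_id]), top$strahler_order)
  }
})

test_that("empirical length ratio recovers r_l within 10% over 20 seeds", {
  hp <- horton_params(r_b = 2, r_l = 2, mean_l1 = 1, max_order = 6,
                      length_cv = 0.2)
  ratios <- vapply(1:20, function(s) {
    net <- generate_network(hp, seed = s)
    top <- network_topology(net)
    lens <- vapply(net$segments, function(x) polyline_length(x$coords), numeric(1))
    ml <- tapply(lens, top$strahler_order, mean)
    exp(mean(diff(log(ml))))  # geometric mean of successive-order ratios
  }, numeric(1))
  expect_lt(abs(mean(ratios) - hp$r_l) / hp$r_l, 0.10)
})

test_that("generators are reproducible: same seed, identical output", {
  hp <- horton_params(max_order = 4, length_cv = 0.3)
  expect_identical(generate_network(hp, seed = 9), generate_network(hp, seed = 9))
  region <- c(0, 100, 0, 100)
  spec <- burn_gen_spec(5)
  expect_identical(generate_burn_scars(region, spec, seed = 2),
                   generate_burn_scars(region, spec, seed = 2))
  expect_identical(generate_ecoregions(region, 4, seed = 3),
                   generate_ecoregions(region, 4, seed = 3))
  ds <- do_sag_spec(c(10, 20, 30), event_times = 100)
  expect_identical(generate_do_series(ds, seed = 4), generate_do_series(ds, seed = 4))
})

test_that("burn scars honour the spec: count, simplicity, patch partition", {
  region <- c(0, 200, 0, 200)
  expect_length(generate_burn_scars(region, burn_gen_spec(0), seed = 1), 0)

  spec <- burn_gen_spec(15)
  scars <- generate_burn_scars(region, spec, seed = 6)
  for (s in scars) {
    expect_true(is_simple_polygon(s$perimeter))
    patch_area <- sum(vapply(Filter(Negate(is.null), s$severity_patches),
                             polygon_area, numeric(1)))
    expect_equal(patch_area, polygon_area(s$perimeter), tolerance = 1e-6)
    expect_true(s$year >= spec$year_range[1] && s$year <= spec$year_range[2])
  }
  # all mass on "high": the high patch is the whole perimeter
  allhigh <- burn_gen_spec(3, severity_fractions = c(
    unburned = 0, low = 0, moderate = 0, high = 1,
    increased_greenness = 0, masked = 0))
  for (s in generate_burn_scars(region, allhigh, seed = 7)) {
    expect_equal(polygon_area(s$severity_patches$high),
                 polygon_area(s$perimeter), tolerance = 1e-9)
  }
})

test_that("per-class area fractions converge to the spec at larger n", {
  region <- c(0, 500, 0, 500)
  spec <- burn_gen_spec(60)
  scars <- generate_burn_scars(region, spec, seed = 8)
  tot <- 0
  by_class <- stats::setNames(numeric(6), severity_classes())
  for (s in scars) {
    tot <- tot + polygon_area(s$perimeter)
    for (cl in severity_classes())
      by_class[cl] <- by_class[cl] + polygon_area(s$severity_patches[[cl]])
  }
  expect_equal(unname(by_class / tot), unname(spec$severity_fractions),
               tolerance = 1e-5)
})

test_that("ecoregion partitions cover the region with no overlap", {
  region <- c(-10, 40, 5, 25)
  one <- generate_ecoregions(region, 1, seed = 1)
  expect_length(one$polygons, 1)
  expect_equal(polygon_area(one$polygons[[1]]),
               (region[2] - region[1]) * (region[4] - region[3]))

  five <- generate_ecoregions(region, 5, seed = 2)
  areas <- vapply(five$polygons, polygon_area, numeric(1))
  expect_equal(sum(areas) / ((region[2] - region[1]) * (region[4] - region[3])),
               1, tolerance = 1e-6)
  # pairwise overlap
  nms <- names(five$polygons)
  for (i in seq_along(nms)[-1]) for (j in seq_len(i - 1)) {
    ov <- intersection_area_convex(five$polygons[[i]], five$polygons[[j]])
    expect_lt(ov / sum(areas), 1e-9)
  }
  expect_error(generate_ecoregions(region, 0, seed = 1), "n_regions")
})

test_that("every scar centroid lands in exactly one ecoregion", {
  region <- c(0, 300, 0, 300)
  emap <- generate_ecoregions(region, 6, seed = 3)
  scars <- generate_burn_scars(region, burn_gen_spec(20), seed = 4)
  for (s in scars) {
    ctr <- polygon_centroid(s$perimeter)
    hits <- sum(vapply(emap$polygons, function(p)
      point_in_polygon(ctr[1], ctr[2], p), logical(1)))
    expect_gte(hits, 1)  # boundary points may touch two rectangles
    # strict-interior membership is unique
    interior <- sum(vapply(emap$polygons, function(p)
      ctr[1] > min(p[, 1]) && ctr[1] < max(p[, 1]) &&
        ctr[2] > min(p[, 2]) && ctr[2] < max(p[, 2]), logical(1)))
    expect_equal(interior, 1)
  }
})

test_that("noiseless DO series hit the closed-form sag magnitude", {
  ds <- do_sag_spec(c(50, 100), baseline_do = 7.2,
                    components = c(a1 = 5, k1 = 0.01, a2 = 0, k2 = 0),
                    event_times = 100, noise_sd = 0)
  ser <- generate_do_series(ds, seed = 1)
  # x = 100: sag magnitude 5 e^(-1)
  expect_equal(7.2 - min(ser[[2]]$do_mgl), 5 * exp(-1), tolerance = 1e-12)
  expect_equal(7.2 - min(ser[[1]]$do_mgl), 5 * exp(-0.5), tolerance = 1e-12)
  # arrival order: time of minimum increases with distance
  tmins <- vapply(ser, function(s) as.numeric(s$time[which.min(s$do_mgl)]),
                  numeric(1))
  expect_true(all(diff(tmins) > 0))
})

test_that("a1 = a2 = 0 yields a flat series at baseline", {
  ds <- do_sag_spec(c(10, 20, 30), baseline_do = 8,
                    components = c(a1 = 0, k1 = 0, a2 = 0, k2 = 0),
                    event_times = 50, noise_sd = 0)
  for (s in generate_do_series(ds, seed = 2))
    expect_true(all(s$do_mgl == 8))
})

test_that("DO series are clipped at 0 and the clipping is reported", {
  ds <- do_sag_spec(c(5), baseline_do = 3,
                    components = c(a1 = 10, k1 = 0.001, a2 = 0, k2 = 0),
                    event_times = 50, noise_sd = 0)
  expect_message(ser <- generate_do_series(ds, seed = 3), "clipped")
  expect_gte(min(ser[[1]]$do_mgl), 0)
  expect_gt(attr(ser, "n_clipped"), 0)
})

test_that("spec validators reject malformed inputs", {
  expect_error(horton_params(r_b = 1), "r_b")
  expect_error(burn_gen_spec(3, severity_fractions = c(
    unburned = 0.5, low = 0.6, moderate = 0, high = 0,
    increased_greenness = 0, masked = 0)), "sum to 1")
  expect_error(do_sag_spec(c(30, 20, 10)))
})
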