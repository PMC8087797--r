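test_that("severity filter keeps only low/moderate/high patches", {
  sq <- rect_polygon(0, 1, 0, 1)
  all_high <- single_class_scar("high", sq)
  expect_equal(polygon_area(severity_filter(all_high)), polygon_area(sq))

  all_unburned <- single_class_scar("unburned", sq)
  expect_equal(polygon_area(severity_filter(all_unburned)), 0)

  # half low / half masked: footprint is half the perimeter area
  hh <- half_half_scar("low", "masked")
  expect_equal(polygon_area(severity_filter(hh)), 0.5)
  # idempotence: filtering the retained classes again changes nothing
  fp <- severity_filter(hh)
  scar2 <- single_class_scar("low", fp$low)
  expect_equal(polygon_area(severity_filter(scar2)), polygon_area(fp))
})

test_that("minimum-area filter removes fires below ~4.1 km^2, keeps ties", {
  rec <- data.frame(fire_id = c("a", "b", "c", "d"),
                    burned_area_km2 = c(2.0, 5.0, 10.0, 4.1))
  out <- apply_min_area_filter(rec)
  expect_equal(out$burned_area_km2, c(5.0, 10.0, 4.1))
  expect_equal(out$fire_id, c("b", "c", "d"))  # order preserved
  expect_identical(apply_min_area_filter(out), out)  # idempotent
  expect_equal(nrow(apply_min_area_filter(rec[0, , drop = FALSE])), 0)
  expect_error(apply_min_area_filter(rec, -1), ">= 0")
})

test_that("clip_length matches analytic cases and respects bounds", {
  sq <- rect_polygon(0, 1, 0, 1)
  net <- line_network(cbind(c(-1, 2), c(0.5, 0.5)), c(-2, 3, -1, 2))
  expect_equal(clip_length(net, sq), 1)
  expect_equal(clip_length(net, rect_polygon(5, 6, 5, 6)), 0)
  # full-region polygon returns the total network length
  hp <- horton_params(max_order = 4, length_cv = 0.2)
  big <- generate_network(hp, seed = 4)
  whole <- rect_polygon(big$region[1], big$region[2], big$region[3], big$region[4])
  expect_equal(clip_length(big, whole), big$total_length_km, tolerance = 1e-9)
  # additivity over disjoint pieces
  left <- rect_polygon(-1, 0.5, 0, 1); right <- rect_polygon(0.5, 2, 0, 1)
  expect_equal(clip_length(net, left) + clip_length(net, right),
               clip_length(net, list(left, right)), tolerance = 1e-12)
  # invalid polygon is rejected with a diagnostic
  bow <- cbind(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0))
  expect_error(clip_length(net, bow), "self-intersecting")
})

test_that("clip_length agrees with the dense-subdivision oracle (50 cases)", {
  hp <- horton_params(r_b = 2, r_l = 2, mean_l1 = 1, max_order = 4,
                      length_cv = 0.25)
  net <- generate_network(hp, seed = 21)
  set.seed(22)
  mids <- lapply(net$segments, function(s)
    s$coords[ceiling(nrow(s$coords) / 2), ])
  for (i in 1:50) {
    ctr <- mids[[sample(length(mids), 1)]] + runif(2, -1, 1)
    scar <- random_convex_polygon(ctr, runif(1, 2, 12))
    got <- clip_length(net, scar)
    want <- oracle_clip_length(net, scar, step = 0.001)
    expect_equal(got, want, tolerance = max(1e-3, 0.002 / max(want, 1e-9)))
  }
})

test_that("clip_length is monotone under footprint enlargement", {
  hp <- horton_params(max_order = 3, length_cv = 0.2)
  net <- generate_network(hp, seed = 30)
  set.seed(31)
  for (i in 1:10) {
    ctr <- net$segments[[sample(length(net$segments), 1)]]$coords[1, ]
    small <- random_convex_polygon(ctr, 3)
    large <- (small - matrix(ctr, nrow(small), 2, byrow = TRUE)) * 2 +
      matrix(ctr, nrow(small), 2, byrow = TRUE)
    expect_gte(clip_length(net, large), clip_length(net, small) - 1e-12)
  }
})

test_that("ecoregion assignment is by largest burned area with lexical ties", {
  emap <- ecoregion_map(list(E1 = rect_polygon(0, 10, 0, 10),
                             E2 = rect_polygon(10, 20, 0, 10)),
                        c(0, 20, 0, 10))
  # 60% in E1, 40% in E2
  expect_equal(assign_ecoregion(rect_polygon(4, 14, 2, 6), emap), "E1")
  expect_equal(assign_ecoregion(rect_polygon(1, 5, 1, 5), emap), "E1")
  # exact 50/50 tie between names A and B -> "A"
  tie <- ecoregion_map(list(B = rect_polygon(0, 10, 0, 10),
                            A = rect_polygon(10, 20, 0, 10)),
                       c(0, 20, 0, 10))
  expect_equal(assign_ecoregion(rect_polygon(5, 15, 2, 6), tie), "A")
  expect_equal(assign_ecoregion(rect_polygon(50, 60, 50, 60), emap), "unassigned")
})

test_that("misattribution fractions follow direct area bookkeeping", {
  emap <- ecoregion_map(list(E1 = rect_polygon(0, 10, 0, 10),
                             E2 = rect_polygon(10, 20, 0, 10)),
                        c(0, 20, 0, 10))
  # fire wholly inside E1
  s1 <- single_class_scar("high", rect_polygon(1, 3, 1, 3), "f1")
  rec1 <- compute_fire_impacts(line_network(cbind(c(0, 20), c(5, 5)),
                                            c(0, 20, 0, 10)),
                               list(s1), emap, min_area = 0)
  mf1 <- misattribution_fraction(rec1, list(s1), emap)
  expect_equal(mf1$fraction[mf1$ecoregion == "E1"], 0)
  # single fire 60/40 across E1/E2, assigned E1: all of E2's burned area is
  # attributed elsewhere
  s2 <- single_class_scar("high", rect_polygon(4, 14, 2, 6), "f2")
  rec2 <- data.frame(fire_id = "f2", year = 2000L, ecoregion = "E1",
                     burned_area_km2 = 40, sl_ba_km = 0,
                     stringsAsFactors = FALSE)
  mf2 <- misattribution_fraction(rec2, list(s2), emap)
  expect_equal(mf2$fraction[mf2$ecoregion == "E2"], 1.0)
  expect_equal(mf2$fraction[mf2$ecoregion == "E1"], 0)
  expect_true(all(mf2$fraction <= 1, na.rm = TRUE))
})

test_that("compute_fire_impacts composes the pipeline stages", {
  region <- c(0, 60, 0, 60)
  hp <- horton_params(r_b = 2, r_l = 2, mean_l1 = 1, max_order = 4,
                      length_cv = 0.2)
  net <- generate_network(hp, seed = 40)
  emap <- generate_ecoregions(net$region, 3, seed = 41)

  expect_equal(nrow(compute_fire_impacts(net, list(), emap)), 0)

  # one scar covering the whole region captures the full network length
  whole <- single_class_scar("moderate",
                             rect_polygon(net$region[1], net$region[2],
                                          net$region[3], net$region[4]),
                             "fAll")
  recs <- compute_fire_impacts(net, list(whole), emap)
  expect_equal(recs$sl_ba_km, net$total_length_km, tolerance = 1e-9)

  # per-fire sl_ba equals clip_length called directly; small fires dropped
  scars <- generate_burn_scars(net$region, burn_gen_spec(12), seed = 42)
  recs2 <- compute_fire_impacts(net, scars, emap)
  expect_true(all(recs2$burned_area_km2 >= 4.1))
  ids <- vapply(scars, function(s) s$fire_id, character(1))
  for (i in seq_len(nrow(recs2))) {
    fp <- severity_filter(scars[[match(recs2$fire_id[i], ids)]])
    expect_equal(recs2$sl_ba_km[i], clip_length(net, fp), tolerance = 1e-12)
  }
  # area basis switch: perimeter area is never below footprint area
  recs3 <- compute_fire_impacts(net, scars, emap, area_basis = "perimeter")
  common <- intersect(recs2$fire_id, recs3$fire_id)
  expect_true(all(recs3$burned_area_km2[match(common, recs3$fire_id)] >=
                    recs2$burned_area_km2[match(common, recs2$fire_id)] - 1e-9))
})

test_that("annual aggregation conserves totals and flags empty cells", {
  rec <- data.frame(
    fire_id = c("a", "b", "c"), year = c(2000L, 2000L, 2002L),
    ecoregion = c("E1", "E1", "E2"),
    burned_area_km2 = c(10, 20, 5), sl_ba_km = c(3, 4, 1),
    stringsAsFactors = FALSE)
  tab <- aggregate_annual(rec)
  expect_equal(sum(tab$burned_area_km2), sum(rec$burned_area_km2))
  expect_equal(sum(tab$sl_ba_km), sum(rec$sl_ba_km))
  # two fires in the same year x ecoregion sum into a single row
  row <- tab[tab$year == 2000 & tab$ecoregion == "E1", ]
  expect_equal(nrow(row), 1)
  expect_equal(row$burned_area_km2, 30)
  expect_equal(row$sl_ba_km, 7)
  expect_equal(row$n_fires, 2L)
  # explicit zero rows for missing combinations, flagged no_fires
  expect_equal(nrow(tab), 3 * 2)  # years 2000:2002 x {E1, E2}
  empty <- tab[tab$year == 2001, ]
  expect_true(all(empty$no_fires))
  expect_true(all(empty$burned_area_km2 == 0))
  # single record
  one <- aggregate_annual(rec[1, ])
  expect_equal(one$burned_area_km2, 10)
})

test_that("drainage table arithmetic and missing-ratio handling", {
  region <- c(0, 5, 0, 1)  # 5 km^2
  net <- stream_network(list(
    list(segment_id = "a", parent_id = NA_character_, strahler_order = 1L,
         coords = cbind(x = c(0, 5), y = c(0.25, 0.25))),
    list(segment_id = "b", parent_id = NA_character_, strahler_order = 1L,
         coords = cbind(x = c(0, 5), y = c(0.75, 0.75)))), region)
  emap <- ecoregion_map(list(E1 = rect_polygon(0, 5, 0, 1)), region)
  ann <- data.frame(year = 2000L, ecoregion = "E1", burned_area_km2 = 0,
                    sl_ba_km = 0, n_fires = 0L, no_fires = TRUE)
  tab <- drainage_ratio_table(emap, net, ann)
  expect_equal(tab$drainage_density, 2.0)  # 10 km in 5 km^2
  expect_true(is.na(tab$slba_ba_ratio))    # no burned area -> missing
})

test_that("uniform burning makes the SL_BA:area ratio approach density", {
  region <- c(0, 100, 0, 100)
  net <- grid_network(region, 50)  # density 0.5 km/km^2
  dens <- net$total_length_km / net$region_area_km2
  set.seed(55)
  ba <- 0; sl <- 0
  for (i in 1:200) {
    w <- runif(1, 5, 15); h <- runif(1, 5, 15)
    x0 <- runif(1, 0, 100 - w); y0 <- runif(1, 0, 100 - h)
    fp <- rect_polygon(x0, x0 + w, y0, y0 + h)
    ba <- ba + w * h
    sl <- sl + clip_length(net, fp)
  }
  expect_lt(abs(sl / ba - dens) / dens, 0.10)
})

test_that("strahler_orders implements the junction rules", {
  # two order-1 tributaries join -> order 2
  topo <- data.frame(segment_id = c("out", "t1", "t2"),
                     parent_id = c(NA, "out", "out"),
                     stringsAsFactors = FALSE)
  expect_equal(unname(strahler_orders(topo)["out"]), 2L)
  # order-1 joins order-3 -> stays 3
  topo2 <- data.frame(
    segment_id = c("out", "big", "small", "b1", "b2", "c1", "c2", "d1", "d2"),
    parent_id = c(NA, "out", "out", "big", "big", "b1", "b1", "b2", "b2"),
    stringsAsFactors = FALSE)
  ord <- strahler_orders(topo2)
  expect_equal(unname(ord["big"]), 3L)
  expect_equal(unname(ord["small"]), 1L)
  expect_equal(unname(ord["out"]), 3L)
  # cycles are rejected
  bad <- data.frame(segment_id = c("a", "b"), parent_id = c("b", "a"),
                    stringsAsFactors = FALSE)
  expect_error(strahler_orders(bad), "cycle")
})

test_that("strahler_orders matches the recursive oracle on random trees", {
  for (s in 1:20) {
    topo <- random_tree(sample(5:50, 1), seed = s)
    got <- strahler_orders(topo)
    want <- oracle_strahler(topo)
    expect_equal(got[order(names(got))], want[order(names(want))])
  }
})
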