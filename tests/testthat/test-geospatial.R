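test_that("deduplication keeps the most recent record per locality", {
  occ <- occurrence_set(data.frame(
    id = c("r1", "r2", "r3"), locality = c("A", "A", "B"),
    date = c("1990", "2010", "2000"), lat = c(1, 1.1, 2), lon = c(1, 1, 2)
  ))
  d <- dedupe_records(occ)
  expect_equal(d$id, c("r2", "r3"))
  # distinct localities are all retained
  occ2 <- occurrence_set(data.frame(
    id = c("a", "b"), locality = c("X", "Y"), date = NA,
    lat = c(0, 1), lon = c(0, 1)
  ))
  expect_equal(nrow(dedupe_records(occ2)), 2)
  # date ties break to the lexicographically smallest id
  occ3 <- occurrence_set(data.frame(
    id = c("z9", "a1"), locality = "L", date = "2005",
    lat = c(0, 0.1), lon = c(0, 0)
  ))
  expect_equal(dedupe_records(occ3)$id, "a1")
  # undated records lose ties to dated ones
  occ4 <- occurrence_set(data.frame(
    id = c("u", "d"), locality = "L", date = c(NA, "1950"),
    lat = c(0, 0.1), lon = c(0, 0)
  ))
  expect_equal(dedupe_records(occ4)$id, "d")
})

test_that("a 3 x 4 km right triangle at the equator has EOO near 6 km2", {
  occ <- occurrence_set(data.frame(
    id = c("a", "b", "c"),
    lat = c(0, 0.0269749, 0), lon = c(0, 0, 0.0359665)
  ))
  expect_equal(eoo_area(occ)$area_km2, 6, tolerance = 0.05 / 6)
})

test_that("EOO equals the geodesic-polygon oracle within one percent", {
  skip_if_not_installed("geosphere")
  set.seed(33)
  for (i in 1:4) {
    occ <- occurrence_set(data.frame(
      id = sprintf("r%02d", 1:15),
      lat = runif(15, -23, -14), lon = runif(15, -46, -40)
    ))
    e <- eoo_area(occ)
    hull <- as.matrix(e$hull[c("lon", "lat")])
    oracle <- geosphere::areaPolygon(hull) / 1e6
    expect_equal(e$area_km2, oracle, tolerance = 0.01)
  }
})

test_that("degenerate point sets get the EOO >= AOO adjustment", {
  occ <- occurrence_set(data.frame(
    id = c("a", "b", "c"), lat = 5, lon = 10
  ))
  expect_equal(eoo_area(occ)$area_km2, 0)
  a <- assess_range(occ, dedupe = FALSE)
  expect_equal(a$assessment$eoo_km2, a$assessment$aoo_km2)
  expect_equal(a$assessment$aoo_km2, 4)
})

test_that("the hull ignores interior points and point order", {
  tri <- data.frame(
    id = c("a", "b", "c", "inner"),
    lat = c(0, 1, 0, 0.3), lon = c(0, 0.5, 1, 0.5)
  )
  e4 <- eoo_area(occurrence_set(tri))
  expect_equal(nrow(e4$hull), 3)
  e3 <- eoo_area(occurrence_set(tri[1:3, ]))
  expect_equal(e4$area_km2, e3$area_km2, tolerance = 1e-12)
  shuffled <- occurrence_set(tri[c(3, 1, 4, 2), ])
  expect_equal(eoo_area(shuffled)$area_km2, e4$area_km2, tolerance = 1e-12)
})

test_that("AOO counts distinct 2-km cells times 4 km2", {
  # two records inside one cell + one elsewhere -> 2 cells = 8 km2
  occ <- occurrence_set(data.frame(
    id = c("a", "b", "c"),
    lat = c(0.001, 0.004, 0.5), lon = c(0.001, 0.004, 0.5)
  ))
  a <- aoo_area(occ)
  expect_equal(a$n_cells, 2)
  expect_equal(a$area_km2, 8)
  # single record
  one <- occurrence_set(data.frame(id = "a", lat = -20, lon = -45))
  expect_equal(aoo_area(one)$area_km2, 4)
  # 19 records in 19 distinct cells -> 76 km2
  set.seed(2)
  o19 <- make_occurrences(n = 19, seed = 2)
  a19 <- aoo_area(o19)
  expect_equal(a19$n_cells, 19)
  expect_equal(a19$area_km2, 76)
})

test_that("AOO is monotone in records and bounded by record count x cell area", {
  o <- make_occurrences(n = 12, seed = 4)
  full <- aoo_area(o)$n_cells
  sub <- aoo_area(o[1:6, ])$n_cells
  expect_lte(sub, full)
  expect_lte(full * 4, 12 * 4)
  # origin-sensitivity scan brackets the default count
  sc <- aoo_area(o, scan = TRUE)
  expect_lte(sc$aoo_min, sc$area_km2)
  expect_gte(sc$aoo_max, sc$area_km2)
})

test_that("criterion-B categories follow the threshold table", {
  expect_equal(iucn_criterion_b(263905, 76)$eoo_category, "LC/NT")
  expect_equal(iucn_criterion_b(263905, 76)$aoo_category, "EN")
  expect_equal(iucn_criterion_b(50, 8)$eoo_category, "CR")
  expect_equal(iucn_criterion_b(50, 8)$aoo_category, "CR")
  expect_equal(iucn_criterion_b(4000, 1500)$eoo_category, "EN")
  expect_equal(iucn_criterion_b(4000, 1500)$aoo_category, "VU")
  expect_equal(iucn_criterion_b(19000, 1999)$eoo_category, "VU")
  # the B2 final call needs both subconditions
  full <- iucn_criterion_b(263905, 76, fragmented = TRUE, declining = TRUE)
  expect_equal(full$category, "EN")
  expect_equal(iucn_criterion_b(263905, 76, fragmented = TRUE)$category, "LC/NT")
  expect_error(iucn_criterion_b(-1, 5), "non-negative")
})

test_that("adding a record inside the hull leaves EOO fixed and AOO near-fixed", {
  o <- make_occurrences(n = 15, seed = 6)
  e <- eoo_area(o)
  centre <- data.frame(
    id = "extra", locality = "extra", date = NA,
    lat = mean(o$lat), lon = mean(o$lon)
  )
  o2 <- occurrence_set(rbind(as.data.frame(o), centre))
  expect_equal(eoo_area(o2)$area_km2, e$area_km2, tolerance = 1e-9)
  diff_cells <- aoo_area(o2)$n_cells - aoo_area(o)$n_cells
  expect_true(diff_cells %in% c(0L, 1L))
})

test_that("dropping a flagged peripheral record shrinks EOO and one AOO cell", {
  o <- make_occurrences(n = 19, outlier = TRUE, seed = 2)
  with_out <- assess_range(o, fragmented = TRUE, declining = TRUE)
  without <- assess_range(o,
    exclude_id = o$id[o$locality == "outlier"],
    fragmented = TRUE, declining = TRUE
  )
  expect_lt(without$assessment$eoo_km2, with_out$assessment$eoo_km2)
  expect_equal(with_out$aoo$n_cells - without$aoo$n_cells, 1L)
  # the categorisation is robust to the removal
  expect_equal(with_out$assessment$category, without$assessment$category)
})
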