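test_that("splits follow the floor(0.75 n) rule and are seed-reproducible", {
  st <- make_rasters(seed = 1)
  pts <- make_niche_presences(st, 8, list(temp = c(18, 21)), seed = 2)
  s1 <- split_presences(pts, st, runs = 5, seed = 9)
  expect_equal(nrow(s1[[1]]$train_p), 6)
  expect_equal(nrow(s1[[1]]$test_p), 2)
  s2 <- split_presences(pts, st, runs = 5, seed = 9)
  expect_identical(s1[[1]]$train_p, s2[[1]]$train_p)
  expect_identical(s1[[3]]$train_b, s2[[3]]$train_b)
  # distinct runs use distinct substreams
  trains <- purrr::map(s1, function(s) sort(s$train_p$lon))
  expect_gt(length(unique(trains)), 1)
  # background excludes presence cells and NODATA
  bg <- s1[[1]]$train_b
  expect_false(any(paste(round(bg$lon, 6), round(bg$lat, 6)) %in%
    paste(round(pts$lon, 6), round(pts$lat, 6))))
  expect_true(all(stats::complete.cases(bg)))
})

test_that("the q = 0 envelope is the min/max box containing all training points", {
  train <- tibble::tibble(a = c(1, 5, 3), b = c(10, 20, 15))
  m <- sre_fit(train, q = 0)
  expect_equal(m$bounds$a, c(1, 5))
  expect_true(all(sre_predict(m, train) == 1))
})

test_that("envelope boundaries follow the linear-interpolation quantile convention", {
  train <- tibble::tibble(a = as.numeric(1:100))
  m <- sre_fit(train, q = 0.025)
  expect_equal(m$bounds$a, quantile(1:100, c(0.025, 0.975), names = FALSE))
  scores <- sre_predict(m, tibble::tibble(a = as.numeric(1:100)))
  expect_true(all(scores[c(1:3, 98:100)] == 0))
  expect_true(all(scores[4:97] == 1))
})

test_that("a two-layer envelope is the intersection of the 1-D envelopes", {
  train <- tibble::tibble(a = c(2, 4, 6, 8), b = c(20, 40, 60, 80))
  m <- sre_fit(train, q = 0)
  grid <- tidyr::expand_grid(a = c(1, 5, 9), b = c(10, 50, 90))
  pred <- sre_predict(m, grid)
  expect_equal(pred, as.numeric(grid$a >= 2 & grid$a <= 8 & grid$b >= 20 & grid$b <= 80))
})

test_that("suitable area is monotone non-increasing in q", {
  st <- make_rasters(seed = 3)
  pts <- make_niche_presences(st, 30, list(temp = c(18, 21)), seed = 4)
  vals <- rs_extract(st, pts$lon, pts$lat)
  areas <- vapply(c(0, 0.05, 0.15), function(q) {
    sum(sre_predict(sre_fit(vals, q = q), st), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("AUC and TSS match their definitions on worked examples", {
  perfect <- evaluate_sdm(c(0.9, 0.8), c(0.3, 0.1))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$tss, 1)
  ex <- evaluate_sdm(c(0.9, 0.7), c(0.8, 0.1))
  expect_equal(ex$auc, 3 / 4)
  flat <- evaluate_sdm(rep(0.5, 4), rep(0.5, 7))
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$tss, 0)
})

test_that("rank-formula AUC equals brute-force pair counting, ties included", {
  set.seed(41)
  for (i in 1:10) {
    sp <- sample(seq(0, 1, 0.1), 12, replace = TRUE)
    sb <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
    expect_equal(evaluate_sdm(sp, sb)$auc, brute_auc(sp, sb), tolerance = 1e-12)
  }
})

test_that("TSS is invariant to monotone transformation of the scores", {
  set.seed(43)
  sp <- runif(10)
  sb <- runif(25)
  base <- evaluate_sdm(sp, sb)
  trans <- evaluate_sdm(exp(3 * sp), exp(3 * sb))
  expect_equal(base$tss, trans$tss, tolerance = 1e-12)
  expect_equal(base$auc, trans$auc, tolerance = 1e-12)
})

test_that("the ensemble keeps only models above the TSS threshold", {
  p1 <- matrix(1, 2, 2)
  p2 <- matrix(0, 2, 2)
  ev <- tibble::tibble(tss = c(0.9, 0.6))
  ens <- sdm_ensemble(list(p1, p2), ev)
  expect_equal(ens$retained, 1L)
  expect_equal(ens$raster, p1)
  # equal weights average plainly
  ev2 <- tibble::tibble(tss = c(0.8, 0.8))
  ens2 <- sdm_ensemble(list(p1, p2), ev2)
  expect_equal(ens2$raster, matrix(0.5, 2, 2))
  expect_error(sdm_ensemble(list(p1), tibble::tibble(tss = 0.3)), "threshold")
})

test_that("projection onto an identical stack is the identity with zero change", {
  st <- make_rasters(seed = 5)
  pts <- make_niche_presences(st, 25, list(temp = c(18, 20)), seed = 6)
  m <- sre_fit(rs_extract(st, pts$lon, pts$lat), q = 0)
  pr <- project_sdm(m, st, st)
  expect_equal(pr$prediction, sre_predict(m, st))
  expect_equal(pr$change_km2, 0)
  expect_equal(pr$change_pct, 0)
  # shifting every layer far outside the envelope empties the range
  far <- shift_rasters(st, c(temp = 100, prec = 1e5))
  expect_equal(project_sdm(m, st, far)$area_future_km2, 0)
  # a missing layer is named in the error
  bad <- raster_stack(list(temp = st$layers$temp), st$extent)
  expect_error(sre_predict(m, bad), "prec")
})

test_that("synthetic warming moves the suitable band poleward", {
  # temp falls with latitude northward (dlat < 0): warming pushes the
  # suitable band toward the cooler (northern, higher-latitude) edge
  st <- make_rasters(
    layers = list(temp = list(base = 24, dlat = -0.8, noise_sd = 0)),
    seed = 7
  )
  pts <- make_niche_presences(st, 30, list(temp = c(18, 20)), seed = 8)
  m <- sre_fit(rs_extract(st, pts$lon, pts$lat), q = 0)
  warm <- shift_rasters(st, c(temp = 2))
  cells <- rs_cells(st)
  centroid_lat <- function(pred) {
    mean(cells$lat[as.vector(t(pred)) == 1])
  }
  lat_now <- centroid_lat(sre_predict(m, st))
  lat_fut <- centroid_lat(project_sdm(m, st, warm)$prediction)
  expect_gt(lat_fut, lat_now)
})
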