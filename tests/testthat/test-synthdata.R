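test_that("one extra generation changes allele frequencies only by drift", {
  # two runs share the RNG stream up to the common generations, so the
  # final-generation frequencies differ by one binomial sampling step
  N <- 200
  base <- function(extra) {
    sim_config(
      census = c(P = N), sample_sizes = c(P = N),
      migration = matrix(1, 1, 1), selfing = 0, n_loci = 5,
      crash = NULL, burnin = 150 + extra, seed = 77
    )
  }
  g0 <- sim_genotypes(base(0))$genotypes
  g1 <- sim_genotypes(base(1))$genotypes
  f0 <- allele_frequencies(g0)
  f1 <- allele_frequencies(g1)
  common <- dplyr::inner_join(f0, f1, by = c("population", "locus", "allele"))
  common <- common[common$freq.x > 0.1 & common$freq.x < 0.9, ]
  z <- abs(common$freq.y - common$freq.x) /
    sqrt(common$freq.x * (1 - common$freq.x) / (2 * N))
  expect_gt(nrow(common), 5)
  expect_gt(mean(z <= 3), 0.9)
})

test_that("obligate selfing drives inbreeding to near fixation", {
  cfg <- sim_config(
    census = c(P = 60), sample_sizes = c(P = 40),
    migration = matrix(1, 1, 1), selfing = 1, n_loci = 8,
    crash = NULL, burnin = 200, seed = 5
  )
  g <- sim_genotypes(cfg)$genotypes
  # after many generations of s = 1 essentially no heterozygotes remain
  het <- mean(g$allele_1 != g$allele_2, na.rm = TRUE)
  expect_lte(het, 0.01)
})

test_that("isolated demes from a common founder diverge under SMM", {
  mig <- diag(2)
  cfg <- sim_config(
    census = c(A = 40, B = 40), sample_sizes = c(A = 15, B = 15),
    migration = mig, selfing = 0, n_loci = 6, model = "smm",
    crash = NULL, burnin = 200, seed = 9
  )
  g <- sim_genotypes(cfg)$genotypes
  a <- amova(g, reps = 199, seed = 1)
  expect_gt(a$fixation, 0)
  expect_lte(a$p, 0.05)
})

test_that("simulation is fully deterministic under the seed", {
  cfg <- sim_config(seed = 123)
  s1 <- sim_genotypes(cfg)
  s2 <- sim_genotypes(cfg)
  expect_identical(s1$genotypes, s2$genotypes)
  expect_identical(s1$truth$migrants, s2$truth$migrants)
  o1 <- make_occurrences(seed = 11)
  o2 <- make_occurrences(seed = 11)
  expect_identical(o1, o2)
  r1 <- make_rasters(seed = 12)
  r2 <- make_rasters(seed = 12)
  expect_identical(r1, r2)
})

test_that("truth logs are consistent with the configuration", {
  cfg <- sim_config(seed = 31)
  sim <- sim_genotypes(cfg)
  expect_equal(
    as.integer(table(sim$truth$deme_of)[names(cfg$census)]),
    as.integer(cfg$sample_sizes)
  )
  expect_equal(
    unname(sim$truth$census_trajectory[nrow(sim$truth$census_trajectory), ]),
    unname(as.integer(cfg$crash$size))
  )
  expect_error(
    sim_config(census = c(P = 10), sample_sizes = c(P = 20), crash = NULL),
    "sample sizes"
  )
  expect_error(sim_config(migration = matrix(0.3, 4, 4)), "sum to 1")
})

test_that("the study-regime preset brackets the target diversity and structure", {
  he <- numeric(25)
  fst <- numeric(25)
  for (r in 1:25) {
    g <- sim_genotypes(sim_config(seed = 3000 + r))$genotypes
    dt <- suppressWarnings(diversity_table(g))
    he[r] <- mean(dt$h_exp[dt$population != "Mean"])
    D <- congenstatus:::copy_distance_matrix(g, "identity", 1)
    key <- dplyr::arrange(
      dplyr::distinct(g, individual, population), population, individual
    )
    pop <- factor(key$population)
    fst[r] <- congenstatus:::amova_components(
      D, rep(as.integer(pop), 2), nlevels(pop)
    )$fixation
  }
  expect_gte(mean(he), 0.25)
  expect_lte(mean(he), 0.60)
  expect_gte(mean(fst), 0.10)
  expect_lte(mean(fst), 0.25)
})

test_that("null-allele injection masks carriers and nulls out homozygotes", {
  g <- make_geno(list(P1 = list(
    "100/100", "100/102", "102/102", "102/104", "104/104", "102/102"
  )))
  inj <- inject_null_alleles(g, "L1", freq = 0.5)
  expect_equal(inj$null_alleles$allele, 102)
  masked <- inj$genotypes
  # former 102-heterozygotes now look homozygous for the visible allele
  expect_equal(masked$allele_1[masked$individual == "P1_i02"], 100L)
  expect_equal(masked$allele_2[masked$individual == "P1_i02"], 100L)
  # former 102/102 homozygotes are missing
  expect_true(is.na(masked$allele_1[masked$individual == "P1_i03"]))
})

test_that("clustered occurrences become uniform as clustering vanishes", {
  o <- make_occurrences(n = 300, clustering = 0, seed = 21)
  # chi-square on a 4 x 4 quadrat grid
  qx <- cut(o$lon, 4)
  qy <- cut(o$lat, 4)
  p <- suppressWarnings(stats::chisq.test(table(qx, qy))$p.value)
  expect_gt(p, 0.01)
  expect_equal(nrow(make_occurrences(n = 1, seed = 3)), 1)
})

test_that("noise-free rasters reproduce the closed-form plane and shifts", {
  st <- make_rasters(
    layers = list(z = list(base = 2, dlon = 3, dlat = 0.5, noise_sd = 0)),
    nrow = 10, ncol = 12, seed = 1
  )
  cells <- rs_cells(st)
  expected <- 2 + 3 * (cells$lon - st$extent[1]) + 0.5 * (cells$lat - st$extent[3])
  expect_equal(as.vector(t(st$layers$z)), expected, tolerance = 1e-12)
  fut <- shift_rasters(st, c(z = 2))
  expect_equal(fut$layers$z - st$layers$z, matrix(2, 10, 12), ignore_attr = TRUE)
})
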