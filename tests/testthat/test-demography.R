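test_that("H_eq is exact in the forced two-copy and monomorphic configurations", {
  h <- heq_distribution(2, 2, "iam", reps = 500, seed = 1)
  expect_true(all(h == 1)) # m = 2, two singletons: (2/1)(1 - 0.5)
  h0 <- heq_distribution(30, 1, "smm", reps = 500, seed = 1)
  expect_true(all(h0 == 0))
})

test_that("IAM H_eq matches the Ewens-sampling-formula oracle given k", {
  oracle <- ewens_heq_given_k(12, 4)
  h <- heq_distribution(12, 4, "iam", reps = 4000, seed = 7)
  se <- sd(h) / sqrt(length(h))
  expect_equal(mean(h), oracle, tolerance = max(4 * se, 0.01))
})

test_that("H_eq means are larger under SMM than IAM at matched k (homoplasy)", {
  for (cfg in list(c(30, 4), c(40, 5))) {
    h_iam <- mean(heq_distribution(cfg[1], cfg[2], "iam", reps = 1500, seed = 3))
    h_smm <- mean(heq_distribution(cfg[1], cfg[2], "smm", reps = 1500, seed = 3))
    expect_gt(h_smm, h_iam)
  }
})

test_that("H_eq samples live in [0, 1) scaled by the unbiased factor", {
  h <- heq_distribution(20, 3, "tpm", reps = 600, seed = 2)
  expect_true(all(h >= 0 & h <= 20 / 19))
  expect_gt(sd(h), 0)
})

test_that("uniform excess across 11 loci drives p to the signed-rank minimum", {
  # 12 maximally heterozygous individuals with balanced allele counts at
  # every locus: H_E far above its equilibrium expectation given k
  mk_locus <- function(k) {
    a1 <- rep(seq_len(k), length.out = 12)
    a2 <- (a1 %% k) + 1L
    cbind(a1 + 100L, a2 + 100L)
  }
  rows <- purrr::map(1:11, function(l) {
    al <- mk_locus(c(3L, 4L, 5L)[(l %% 3) + 1])
    tibble::tibble(
      individual = sprintf("i%02d", 1:12), population = "P1",
      locus = sprintf("L%02d", l), allele_1 = al[, 1], allele_2 = al[, 2]
    )
  })
  g <- geno_tbl(dplyr::bind_rows(rows))
  bt <- bottleneck_test(g, models = "iam", reps = 800, seed = 1)
  expect_true(all(bt$per_locus$dh > 0))
  # all 11 standardized differences positive: one-tailed signed-rank
  # p <= 1/2^11 < 0.005
  expect_lte(bt$summary$p, 0.005)
})

test_that("a strong recent census crash is detected as heterozygosity excess", {
  cfg <- sim_config(
    census = c(P1 = 500), sample_sizes = c(P1 = 8),
    migration = matrix(1, 1, 1), selfing = 0, n_loci = 11,
    crash = list(when = 3, size = c(P1 = 8)), burnin = 4000, seed = 101
  )
  g <- sim_genotypes(cfg)$genotypes
  bt <- bottleneck_test(g, models = "iam", reps = 500, seed = 1)
  expect_lt(bt$summary$p, 0.05)
})

test_that("bottleneck testing refuses populations with too few polymorphic loci", {
  g <- make_geno(list(P1 = purrr::map(1:6, function(i) {
    c("100/100", "100/102", "104/106", "100/100")
  })))
  expect_error(bottleneck_test(g, reps = 500), "polymorphic")
})

test_that("Eq. 1 hand cases reproduce the printed arithmetic", {
  # n = 1, non-inbred: Theta = 0.5(1 + 0)/1 = 0.5, Ne = 1
  r1 <- coancestry_ne(0, matrix(0, 1, 1))
  expect_equal(r1$theta_group, 0.5)
  expect_equal(r1$ne, 1)
  # n = 2 unrelated non-inbred: Theta = (0.5 + 0.5 + 0)/4 = 0.25, Ne = 2
  r2 <- coancestry_ne(c(0, 0), matrix(0, 2, 2))
  expect_equal(r2$theta_group, 0.25)
  expect_equal(r2$ne, 2)
  # non-positive Theta is flagged, not inverted
  expect_warning(r3 <- coancestry_ne(c(-1, -1), matrix(0, 2, 2)))
  expect_true(is.na(r3$ne))
})

# two moderately diverged demes; kinship referenced to the pooled sample
two_deme_geno <- function(seed = 4, n_loci = 10) {
  mig <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2)
  cfg <- sim_config(
    census = c(A = 40, B = 40), sample_sizes = c(A = 20, B = 20),
    migration = mig, selfing = 0, n_loci = n_loci, crash = NULL,
    burnin = 500, seed = seed
  )
  sim_genotypes(cfg)$genotypes
}

test_that("kinship matrices are symmetric and Theta is assembled from them", {
  g <- two_deme_geno(seed = 4)
  for (est in c("loiselle", "ritland")) {
    co <- group_coancestry(g, "A", estimator = est)
    expect_true(isSymmetric(co$kinship, tol = 1e-12))
    expect_true(all(co$f_i$f >= -1 & co$f_i$f <= 1))
    expect_gt(co$theta_group, 0)
    manual <- coancestry_ne(co$f_i$f, co$kinship)
    expect_equal(co$theta_group, manual$theta_group)
  }
})

test_that("a sample-centred reference collapses Theta to 1/(2n - 1)", {
  # with the analysed population itself as reference, the Eq. 1 terms
  # cancel and Ne is n - 0.5 whatever the genotypes
  g <- two_deme_geno(seed = 6)
  co <- group_coancestry(g, "A", reference = "within")
  expect_equal(co$theta_group, 1 / (2 * 20 - 1), tolerance = 1e-6)
  expect_equal(co$ne, 19.5, tolerance = 1e-3)
})

test_that("close relatives in the sample lower the coancestry N_E", {
  # at fixed sample size, a sample containing a full-sib family gives a
  # smaller N_E than an equal-sized sample of population members (Eq. 1's
  # self terms scale with n, so n is held constant in the comparison)
  for (s in 1:3) {
    mig <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
    cfg <- sim_config(
      census = c(A = 40, B = 40), sample_sizes = c(A = 20, B = 20),
      migration = mig, selfing = 0, n_loci = 10, crash = NULL,
      burnin = 400, seed = s
    )
    g <- sim_genotypes(cfg)$genotypes
    ne_base <- group_coancestry(g, "A")$ne
    set.seed(15)
    ids <- unique(g$individual[g$population == "A"])
    p1 <- g[g$individual == ids[1], ]
    p2 <- g[g$individual == ids[2], ]
    sibs <- purrr::map(1:10, function(i) {
      pick <- function(p) ifelse(runif(nrow(p)) < 0.5, p$allele_1, p$allele_2)
      tibble::tibble(
        individual = sprintf("sib_%02d", i), population = "A",
        locus = p1$locus, allele_1 = pick(p1), allele_2 = pick(p2)
      )
    })
    keep <- g$individual %in% ids[1:10] | g$population == "B"
    g_sibs <- geno_tbl(dplyr::bind_rows(as.data.frame(g[keep, ]), sibs))
    ne_sibs <- group_coancestry(g_sibs, "A")$ne
    expect_lt(ne_sibs, ne_base)
  }
})

test_that("mutation-scaled conversions are exact arithmetic", {
  expect_equal(nem_from_theta_m(0.4, 10), 1)
  expect_equal(nem_from_theta_m(0.2, 0), 0)
  # the reported migrant-number range follows the same arithmetic
  expect_equal(nem_from_theta_m(0.344, 1), 0.086)
  expect_equal(historical_ne(0.01904, mu = 4.76e-3), 1)
  expect_equal(historical_ne(9.158), 481, tolerance = 1e-3)
  expect_equal(historical_ne(0), 0)
  expect_error(historical_ne(1, mu = 0), "positive")
  expect_error(nem_from_theta_m(-1, 2), "non-negative")
  # round-trip: Theta = 4 Ne mu recovers Ne to machine precision
  for (ne in c(11, 481, 760)) {
    expect_equal(historical_ne(4 * ne * 4.76e-3), ne, tolerance = 1e-12)
  }
})
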