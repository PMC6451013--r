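# a small two-population dataset with disjoint fixed alleles
disjoint_geno <- function(n_per = 10, n_loci = 5) {
  make_geno(list(
    A = purrr::map(seq_len(n_per), function(i) rep("100/100", n_loci)),
    B = purrr::map(seq_len(n_per), function(i) rep("200/200", n_loci))
  ))
}

test_that("K = 1 is degenerate: Q = 1 and ln L matches the pooled closed form", {
  set.seed(3)
  g <- hwe_geno(n = 15, n_loci = 4)
  r <- run_admixture(g, K = 1, burnin = 300, iters = 1500, seed = 2)
  expect_true(all(r$Q$q_1 == 1))
  # closed form: E[ln L] under the Dirichlet posterior of pooled frequencies
  f <- allele_frequencies(g)
  exact <- sum(purrr::map_dbl(split(f, f$locus), function(d) {
    sum(d$count * (digamma(d$count + 1) - digamma(d$m[1] + nrow(d))))
  }))
  mle <- sum(log(rep(f$freq, f$count)))
  ll <- congenstatus:::run_loglik(r)
  expect_equal(ll, exact, tolerance = 0.01 * abs(exact))
  expect_equal(ll, mle, tolerance = 0.03 * abs(mle))
})

test_that("disjoint gene pools separate cleanly at K = 2", {
  g <- disjoint_geno()
  r <- run_admixture(g, K = 2, burnin = 300, iters = 1200, seed = 5)
  qmax <- apply(as.matrix(r$Q[c("q_1", "q_2")]), 1, max)
  expect_true(all(qmax >= 0.95))
  # cluster assignment agrees with the true populations
  modal <- apply(as.matrix(r$Q[c("q_1", "q_2")]), 1, which.max)
  expect_equal(length(unique(modal[r$Q$population == "A"])), 1)
  expect_true(modal[r$Q$population == "A"][1] != modal[r$Q$population == "B"][1])
})

test_that("an admixed individual's Q is recovered within tolerance", {
  # two divergent pools fixed for different alleles at 20 loci, plus one
  # individual heterozygous everywhere: true q = (0.5, 0.5)
  n_loci <- 20
  pools <- list(
    A = purrr::map(1:10, function(i) rep("100/100", n_loci)),
    B = purrr::map(1:10, function(i) rep("200/200", n_loci))
  )
  g <- make_geno(pools)
  mix <- tibble::tibble(
    individual = "mix_01", population = "MIX",
    locus = sprintf("L%d", 1:n_loci), allele_1 = 100L, allele_2 = 200L
  )
  g <- geno_tbl(dplyr::bind_rows(as.data.frame(g), mix))
  qs <- vapply(1:10, function(s) {
    r <- run_admixture(g, K = 2, burnin = 200, iters = 1000, seed = s)
    unlist(r$Q[r$Q$population == "MIX", "q_1"])
  }, 0)
  expect_equal(mean(pmin(qs, 1 - qs)), 0.5, tolerance = 0.15)
})

test_that("the likelihood trace is stationary after burn-in", {
  g <- disjoint_geno()
  r <- run_admixture(g, K = 2, burnin = 500, iters = 2500, seed = 9)
  keep <- r$loglik[501:2500]
  expect_true(all(is.finite(keep)))
  # Geweke-style split comparison: halves differ by < 3 pooled sds
  a <- keep[1:1000]
  b <- keep[1001:2000]
  pooled_se <- sqrt(var(a) / 1000 + var(b) / 1000)
  expect_lt(abs(mean(a) - mean(b)), 3 * max(pooled_se, 1e-6) + 0.5)
})

test_that("a large fixed alpha drives memberships toward uniformity", {
  g <- disjoint_geno(n_per = 6, n_loci = 2)
  r <- run_admixture(g, K = 2, burnin = 300, iters = 1200, seed = 4,
                     alpha_mode = "fixed", alpha = 100)
  qmax <- apply(as.matrix(r$Q[c("q_1", "q_2")]), 1, max)
  expect_lt(mean(qmax), 0.75)
})

test_that("Evanno delta-K reproduces the hand-computed second difference", {
  fake_run <- function(K, ll) {
    structure(list(K = K, loglik = ll, burnin = 0, iters = length(ll),
                   Q = NULL), class = "cluster_run")
  }
  runs <- list(
    fake_run(2, c(-101, -99)), fake_run(2, c(-99, -101)),
    fake_run(3, c(-92, -88)), fake_run(3, c(-88, -92)),
    fake_run(4, c(-87, -89)), fake_run(4, c(-89, -87))
  )
  # means: -100, -90, -88; sd at K = 3 is sd(c(-90, -90)) = 0 -> guarded
  sel <- select_k(runs)
  expect_equal(sel$mean_loglik, c(-100, -90, -88))
  # replicate means are equal so sd = 0 and the epsilon guard applies
  expect_true(is.na(sel$delta_k[1]) && is.na(sel$delta_k[3]))
  # now with spread replicates giving sd(K = 3) = 2
  runs2 <- list(
    fake_run(2, -100), fake_run(2, -100),
    fake_run(3, -88.58579), fake_run(3, -91.41421), # mean -90, sd 2
    fake_run(4, -88), fake_run(4, -88)
  )
  sel2 <- select_k(runs2)
  expect_equal(sel2$delta_k[2], abs(-88 + 180 - 100) / 2, tolerance = 1e-4)
  expect_equal(attr(sel2, "k_delta"), 3)
})

test_that("identical likelihoods across runs give delta-K of zero", {
  fake_run <- function(K) {
    structure(list(K = K, loglik = c(-50, -50), burnin = 0, iters = 2),
              class = "cluster_run")
  }
  runs <- purrr::flatten(purrr::map(2:4, function(K) list(fake_run(K), fake_run(K))))
  sel <- select_k(runs)
  expect_equal(sel$delta_k[2], 0)
})

test_that("label alignment averages runs up to cluster permutation", {
  mk_run <- function(qmat, K = 2) {
    q <- tibble::tibble(
      individual = sprintf("i%d", seq_len(nrow(qmat))),
      population = "P"
    )
    q[paste0("q_", seq_len(K))] <- as.data.frame(qmat)
    structure(list(K = K, Q = q), class = "cluster_run")
  }
  r1 <- mk_run(rbind(c(1, 0), c(1, 0)))
  r2 <- mk_run(rbind(c(0.1, 0.9), c(0.1, 0.9))) # labels flipped
  avg <- align_runs(list(r1, r2))
  expect_equal(avg$q_1, c(0.95, 0.95))
  expect_equal(avg$q_2, c(0.05, 0.05))
  # two identical runs up to label swap average to either run
  r3 <- mk_run(rbind(c(0.8, 0.2), c(0.3, 0.7)))
  r4 <- mk_run(rbind(c(0.2, 0.8), c(0.7, 0.3)))
  avg2 <- align_runs(list(r3, r4))
  expect_equal(avg2$q_1, c(0.8, 0.3))
  # K = 1 alignment is the identity
  r5 <- mk_run(matrix(1, 2, 1), K = 1)
  expect_equal(align_runs(list(r5, r5))$q_1, c(1, 1))
})

test_that("posterior means are invariant in distribution to relabeling", {
  g <- disjoint_geno(n_per = 8, n_loci = 4)
  runs <- purrr::map(1:3, function(s) {
    run_admixture(g, K = 2, burnin = 200, iters = 800, seed = s)
  })
  avg <- align_runs(runs)
  qmax <- apply(as.matrix(avg[c("q_1", "q_2")]), 1, max)
  expect_true(all(qmax > 0.9)) # alignment undoes any label switching
})

test_that("admixture summaries count individuals below the modal-Q threshold", {
  q <- tibble::tibble(
    individual = c("a", "b", "c"), population = "P",
    q_1 = c(0.95, 0.7, 0.5), q_2 = c(0.05, 0.3, 0.5)
  )
  s <- admixture_summary(q, threshold = 0.9)
  expect_equal(s$n_admixed, 2L)
})
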