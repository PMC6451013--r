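# Fixture builders and independent oracles shared across the suite.

# Build a geno_tbl from per-population genotype strings:
# pops = list(P1 = list(c("100/102", "100/100", ...), ...)) where each
# inner character vector is one individual's genotypes across loci
# ("NA" = missing call).
make_geno <- function(pops, loci = NULL) {
  rows <- list()
  for (p in names(pops)) {
    for (i in seq_along(pops[[p]])) {
      gts <- pops[[p]][[i]]
      if (is.null(loci)) loci <- sprintf("L%d", seq_along(gts))
      al <- t(vapply(strsplit(gts, "/"), function(v) {
        if (identical(v[1], "NA")) c(NA_integer_, NA_integer_) else as.integer(v)
      }, integer(2)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = sprintf("%s_i%02d", p, i), population = p,
        locus = loci, allele_1 = al[, 1], allele_2 = al[, 2]
      )
    }
  }
  geno_tbl(dplyr::bind_rows(rows))
}

# Random-mating population: genotypes drawn from HWE at Dirichlet-random
# allele frequencies (one population, `n` individuals, `n_loci` loci).
hwe_geno <- function(n = 30, n_loci = 5, n_alleles = 4, pop = "P1") {
  rows <- purrr::map(seq_len(n_loci), function(l) {
    f <- rgamma(n_alleles, 1)
    f <- f / sum(f)
    a1 <- sample.int(n_alleles, n, replace = TRUE, prob = f) + 100L
    a2 <- sample.int(n_alleles, n, replace = TRUE, prob = f) + 100L
    tibble::tibble(
      individual = sprintf("%s_i%02d", pop, seq_len(n)), population = pop,
      locus = sprintf("L%d", l), allele_1 = a1, allele_2 = a2
    )
  })
  geno_tbl(dplyr::bind_rows(rows))
}

# Random genotype dataset for round-trip tests (allele codes < 1000 so the
# 3-digit GenePop encoding applies; some missing calls).
random_geno <- function(n_pop = 2, n_ind = 4, n_loci = 3, p_missing = 0.1) {
  rows <- list()
  for (p in seq_len(n_pop)) {
    for (i in seq_len(n_ind)) {
      a1 <- sample(100:140, n_loci, replace = TRUE)
      a2 <- sample(100:140, n_loci, replace = TRUE)
      miss <- runif(n_loci) < p_missing
      a1[miss] <- NA_integer_
      a2[miss] <- NA_integer_
      rows[[length(rows) + 1]] <- tibble::tibble(
        individual = sprintf("p%d_i%d", p, i), population = sprintf("pop%d", p),
        locus = sprintf("loc%d", seq_len(n_loci)), allele_1 = a1, allele_2 = a2
      )
    }
  }
  geno_tbl(dplyr::bind_rows(rows))
}

# Brute-force one-level AMOVA from an explicitly assembled copy-level
# distance matrix (independent of the package's vectorised path).
brute_amova <- function(x, metric = "identity") {
  key <- dplyr::arrange(
    dplyr::distinct(x, individual, population), population, individual
  )
  loci <- sort(unique(x$locus))
  n <- nrow(key)
  copies <- list()
  for (i in seq_len(n)) {
    sub <- x[x$individual == key$individual[i], ]
    sub <- sub[match(loci, sub$locus), ]
    copies[[i]] <- sub$allele_1
    copies[[n + i]] <- sub$allele_2
  }
  cpop <- rep(key$population, 2)
  N <- 2 * n
  D <- matrix(0, N, N)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      d <- 0
      for (l in seq_along(loci)) {
        a <- copies[[i]][l]
        b <- copies[[j]][l]
        if (is.na(a) || is.na(b)) next
        d <- d + if (metric == "identity") (a != b) else (a - b)^2
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  pops <- unique(cpop)
  P <- length(pops)
  ssd_t <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) ssd_t <- ssd_t + D[i, j]
  ssd_t <- ssd_t / N
  ssd_w <- 0
  for (p in pops) {
    idx <- which(cpop == p)
    s <- 0
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (ii < jj) s <- s + D[idx[ii], idx[jj]]
      }
    }
    ssd_w <- ssd_w + s / length(idx)
  }
  ssd_a <- ssd_t - ssd_w
  n_p <- table(cpop)[pops]
  ms_a <- ssd_a / (P - 1)
  ms_w <- ssd_w / (N - P)
  n_c <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_a <- (ms_a - ms_w) / n_c
  list(sigma_a = sigma_a, sigma_w = ms_w, fst = sigma_a / (sigma_a + ms_w))
}

# Brute-force AUC by counting presence/background pairs (ties = 0.5).
brute_auc <- function(sp, sb) {
  tot <- 0
  for (p in sp) {
    for (b in sb) {
      tot <- tot + if (p > b) 1 else if (p == b) 0.5 else 0
    }
  }
  tot / (length(sp) * length(sb))
}

# Exact E[H_eq | k alleles] under the infinite-allele model: the allele
# configuration given k is theta-free (Ewens sampling formula), so the
# expectation is a weighted mean over the integer partitions of n with
# exactly k parts, with weight prod(1 / (j^a_j * a_j!)).
ewens_heq_given_k <- function(n, k) {
  parts <- partitions_k(n, k)
  ws <- vapply(parts, function(p) {
    tab <- table(p)
    1 / prod(as.numeric(names(tab))^tab * factorial(tab))
  }, 0)
  hs <- vapply(parts, function(p) {
    n / (n - 1) * (1 - sum((p / n)^2))
  }, 0)
  sum(ws * hs) / sum(ws)
}

# integer partitions of n into exactly k parts (non-increasing)
partitions_k <- function(n, k, max_part = n) {
  if (k == 1) {
    if (n <= max_part) return(list(n)) else return(list())
  }
  out <- list()
  for (first in seq(min(max_part, n - k + 1), 1)) {
    for (rest in partitions_k(n - first, k - 1, first)) {
      out[[length(out) + 1]] <- c(first, rest)
    }
  }
  out
}

# Single-deme forward simulation at mutation-drift equilibrium.
equilibrium_geno <- function(n_sample = 20, census = 25, n_loci = 6,
                             mu = 4.76e-3, model = "iam", seed = 1,
                             selfing = 0) {
  cfg <- sim_config(
    census = c(P1 = census), sample_sizes = c(P1 = n_sample),
    migration = matrix(1, 1, 1), selfing = selfing, n_loci = n_loci,
    mu = mu, model = model, crash = NULL, burnin = 12L * census, seed = seed
  )
  sim_genotypes(cfg)$genotypes
}
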