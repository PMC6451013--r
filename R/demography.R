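#' Equilibrium heterozygosity distribution given an observed allele count
#'
#' Simulates coalescent genealogies of `n_copies` gene copies with
#' mutations under the chosen microsatellite model. The mutation parameter
#' is first calibrated by bisection so that the mean simulated allele count
#' matches `k_alleles` (tolerance 0.05); replicates are then retained only
#' when the realized allele count equals `k_alleles` exactly. Each retained
#' replicate yields \eqn{H_{eq} = m/(m-1)\,(1 - \sum p^2)}. This is the
#' null distribution of the heterozygosity-excess bottleneck test.
#'
#' @param n_copies Number of gene copies m (sample size x 2).
#' @param k_alleles Observed allele count, between 1 and `n_copies`.
#' @param model `"iam"`, `"smm"` or `"tpm"`.
#' @param reps Retained replicates, at least 500.
#' @param seed Integer seed.
#' @param p_multi TPM multi-step fraction (default 0.30).
#' @param p_geom Geometric parameter of the multi-step length (default 1/6,
#'   i.e. step variance 30).
#' @return Numeric vector of `reps` H_eq values, with the calibrated theta
#'   as attribute `theta`.
#' @export
heq_distribution <- function(n_copies, k_alleles, model = c("iam", "smm", "tpm"),
                             reps = 1000, seed = 1, p_multi = 0.3,
                             p_geom = 1 / 6) {
  model <- match.arg(model)
  if (reps < 500) abort("reps must be at least 500")
  if (k_alleles < 1 || k_alleles > n_copies) {
    abort("need 1 <= k_alleles <= n_copies")
  }
  if (k_alleles == 1) {
    return(structure(rep(0, reps), theta = 0))
  }
  mcode <- match(model, c("iam", "smm", "tpm")) - 1L
  with_seed(seed, {
    sim_k <- function(theta, n) {
      mean(cpp_coalescent_sim(n_copies, theta, mcode, p_multi, p_geom, n)$k)
    }
    # bracket the target mean allele count
    lo <- 1e-4
    hi <- 1
    tries <- 0
    while (sim_k(hi, 400) < k_alleles && tries < 25) {
      hi <- hi * 2
      tries <- tries + 1
    }
    if (tries == 25) {
      abort(sprintf(
        "calibration cannot reach k = %d with n = %d under %s (size homoplasy); no bracket found",
        k_alleles, n_copies, model
      ))
    }
    theta <- hi
    for (i in 1:30) {
      theta <- sqrt(lo * hi) # bisect on log scale
      mk <- sim_k(theta, 1200)
      if (abs(mk - k_alleles) <= 0.05) break
      if (mk < k_alleles) lo <- theta else hi <- theta
    }
    # exact-k rejection sampling at the calibrated theta
    kept <- numeric(0)
    attempts <- 0
    while (length(kept) < reps && attempts < 400) {
      sim <- cpp_coalescent_sim(n_copies, theta, mcode, p_multi, p_geom, 4000L)
      kept <- c(kept, sim$het[sim$k == k_alleles])
      attempts <- attempts + 1
    }
    if (length(kept) < reps) {
      abort(sprintf(
        "exact-k rejection too inefficient for k = %d, n = %d under %s",
        k_alleles, n_copies, model
      ))
    }
    structure(n_copies / (n_copies - 1) * kept[seq_len(reps)], theta = theta)
  })
}

#' Heterozygosity-excess bottleneck test
#'
#' For every polymorphic locus of a population, the observed unbiased H_E
#' is compared with the mutation-drift-equilibrium distribution of H_eq
#' conditional on the observed allele count ([heq_distribution()]); the
#' standardized difference \eqn{DH = (H_E - \bar H_{eq}) / sd\,H_{eq}} is
#' computed per locus and a one-tailed Wilcoxon signed-rank test over loci
#' assesses the alternative that H_E exceeds H_eq (a recent-bottleneck
#' signature). Summaries N (mean gene copies per sample) and k (mean
#' equilibrium allele count) are reported per population and model.
#'
#' @param x A [geno_tbl()].
#' @param populations Populations to test (default all).
#' @param models Mutation models to run, a subset of
#'   `c("iam", "tpm", "smm")`.
#' @param reps Retained equilibrium replicates per locus.
#' @param seed Integer seed.
#' @param p_multi,p_geom TPM settings, see [heq_distribution()].
#' @param cache Optional environment memoising H_eq distributions across
#'   calls (keyed by copies x alleles x model).
#' @return A `bottleneck_result` with `per_locus` and `summary` tibbles.
#' @export
bottleneck_test <- function(x, populations = NULL,
                            models = c("iam", "tpm", "smm"), reps = 1000,
                            seed = 1, p_multi = 0.3, p_geom = 1 / 6,
                            cache = NULL) {
  models <- match.arg(models, several.ok = TRUE)
  populations <- populations %||% unique(x$population)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  per_locus <- list()
  summary <- list()
  for (pop in populations) {
    cc <- pop_locus_cells(x[x$population == pop, ])
    cc <- cc[cc$n_typed > 0, ]
    cc$m <- 2L * cc$n_typed
    cc$k <- vapply(cc$copies, function(v) length(unique(v)), 1L)
    poly <- cc[cc$k >= 2, ]
    if (nrow(poly) < 4) {
      abort(sprintf(
        "population '%s' has %d polymorphic loci; the Wilcoxon test needs at least 4 (consider an exact sign test)",
        pop, nrow(poly)
      ))
    }
    for (model in models) {
      rows <- purrr::pmap(poly, function(population, locus, n_typed, n_het, copies, m, k) {
        key <- sprintf("%d|%d|%s|%g|%g|%d", m, k, model, p_multi, p_geom, reps)
        if (is.null(cache[[key]])) {
          cache[[key]] <- heq_distribution(
            m, k, model,
            reps = reps,
            seed = seed + m * 1000L + k, p_multi = p_multi, p_geom = p_geom
          )
        }
        heq <- cache[[key]]
        he <- unbiased_he(as.numeric(table(copies)))
        tibble(
          population = population, model = model, locus = locus,
          m = m, k = k, h_exp = he,
          heq_mean = mean(heq), heq_sd = stats::sd(heq),
          dh = (he - mean(heq)) / stats::sd(heq)
        )
      })
      rows <- dplyr::bind_rows(rows)
      p <- suppressWarnings(
        wilcox.test(rows$dh, alternative = "greater", exact = nrow(rows) <= 25)$p.value
      )
      per_locus[[length(per_locus) + 1L]] <- rows
      summary[[length(summary) + 1L]] <- tibble(
        population = pop, model = model, p = p,
        n_loci = nrow(rows),
        mean_copies = mean(cc$m), mean_k = mean(rows$k)
      )
    }
  }
  structure(
    list(
      per_locus = dplyr::bind_rows(per_locus),
      summary = dplyr::bind_rows(summary)
    ),
    class = "bottleneck_result"
  )
}

#' @export
print.bottleneck_result <- function(x, ...) {
  cat("Heterozygosity-excess bottleneck test (one-tailed Wilcoxon)\n")
  print(x$summary)
  invisible(x)
}

#' @rdname bottleneck_test
#' @param ... Unused.
#' @export
tidy.bottleneck_result <- function(x, ...) x$per_locus

#' @rdname bottleneck_test
#' @export
glance.bottleneck_result <- function(x, ...) x$summary

#' Contemporary effective size from group coancestry
#'
#' Estimates the pairwise kinship matrix \eqn{\theta_{ij}} of a sampled
#' population with a marker-based estimator (Loiselle by default, Ritland
#' selectable) using within-population allele frequencies as reference,
#' derives individual inbreeding from self-kinship
#' (\eqn{\hat F_i = 2\hat\theta_{ii} - 1}, clamped to \[-1, 1\]), assembles
#' the group coancestry
#' \deqn{\Theta = \left[\sum_i 0.5 (1 + F_i) + \sum_i \sum_{j \ne i}
#'   \theta_{ij}\right] / n^2}
#' and reports the contemporary effective size \eqn{N_E = 0.5 / \Theta}.
#'
#' @details
#' With `reference = "within"` every kinship is centred on the analysed
#' sample itself; the diagonal and off-diagonal terms of Eq. 1 then cancel
#' algebraically and \eqn{\Theta} reduces to \eqn{1/(2n-1)} whatever the
#' genotypes (so \eqn{N_E \approx n - 0.5}). The default `"global"`
#' reference (allele frequencies over the whole dataset, as SPAGeDi
#' computes them) keeps \eqn{\Theta} sensitive to inbreeding and
#' relatedness within the population.
#'
#' @param x A [geno_tbl()]; all populations present contribute to the
#'   reference allele frequencies.
#' @param population Population to analyse (default: the first).
#' @param estimator `"loiselle"` or `"ritland"`.
#' @param reference `"global"` (whole-dataset allele frequencies, default)
#'   or `"within"` (the analysed population only).
#' @return A `coancestry_ne` list: `theta_group`, `ne`, `f_i` tibble,
#'   `kinship` matrix, `estimator`, `n`.
#' @export
group_coancestry <- function(x, population = NULL,
                             estimator = c("loiselle", "ritland"),
                             reference = c("global", "within")) {
  estimator <- match.arg(estimator)
  reference <- match.arg(reference)
  population <- population %||% unique(x$population)[1]
  sub <- x[x$population == population, ]
  ids <- unique(sub$individual)
  n <- length(ids)
  if (n < 2) abort("group_coancestry needs at least 2 individuals")
  ref <- if (reference == "global") x else sub
  K <- kinship_matrix(sub, ids, estimator, ref)
  f_i <- pmin(pmax(2 * diag(K) - 1, -1), 1)
  res <- coancestry_ne(f_i, K)
  structure(
    c(res, list(
      f_i = tibble(individual = ids, f = f_i),
      kinship = K, estimator = estimator, n = n, population = population
    )),
    class = "coancestry_ne"
  )
}

#' Assemble group coancestry and N_E from kinship components
#'
#' The arithmetic core of [group_coancestry()]: given individual inbreeding
#' coefficients and a pairwise kinship matrix, computes
#' \eqn{\Theta = [\sum_i 0.5(1+F_i) + \sum_{i \ne j} \theta_{ij}] / n^2}
#' and \eqn{N_E = 0.5/\Theta}. A non-positive \eqn{\Theta} (possible with
#' noisy estimators on small samples) yields `ne = NA` with a warning.
#'
#' @param f_i Numeric vector of individual inbreeding coefficients.
#' @param kinship Symmetric n x n kinship matrix (diagonal unused).
#' @return A list with `theta_group` and `ne`.
#' @examples
#' coancestry_ne(0, matrix(0, 1, 1)) # n = 1: Theta = 0.5, Ne = 1
#' @export
coancestry_ne <- function(f_i, kinship) {
  n <- length(f_i)
  off <- kinship
  diag(off) <- 0
  theta <- (sum(0.5 * (1 + f_i)) + sum(off)) / n^2
  ne <- if (theta > 0) {
    0.5 / theta
  } else {
    warn("group coancestry is non-positive; N_E undefined")
    NA_real_
  }
  list(theta_group = theta, ne = ne)
}

#' @export
print.coancestry_ne <- function(x, ...) {
  cat(sprintf(
    "Group coancestry (%s): Theta = %.4f, contemporary N_E = %.1f (n = %d)\n",
    x$estimator, x$theta_group, x$ne, x$n
  ))
  invisible(x)
}

#' @rdname group_coancestry
#' @param ... Unused.
#' @export
glance.coancestry_ne <- function(x, ...) {
  tibble(
    population = x$population, estimator = x$estimator, n = x$n,
    theta_group = x$theta_group, ne = x$ne, mean_f = mean(x$f_i$f)
  )
}

# pairwise kinship matrix (including self-kinship on the diagonal),
# pairwise-available over loci; reference allele frequencies from `ref`
kinship_matrix <- function(sub, ids, estimator, ref = sub) {
  loci <- sort(unique(sub$locus))
  n <- length(ids)
  ref_freq <- allele_frequencies(ref)
  # per-locus: individual dosage matrix (n x A) with NA rows when missing
  locdat <- purrr::map(loci, function(l) {
    s <- sub[sub$locus == l, ]
    s <- s[match(ids, s$individual), ]
    fr <- ref_freq[ref_freq$locus == l, ]
    lev <- sort(unique(fr$allele))
    if (length(lev) < 2) return(NULL)
    cnt <- vapply(lev, function(a) sum(fr$count[fr$allele == a]), 0)
    pbar <- cnt / sum(cnt)
    P <- matrix(NA_real_, n, length(lev))
    ok <- !is.na(s$allele_1)
    P[ok, ] <- 0
    for (i in which(ok)) {
      P[i, match(s$allele_1[i], lev)] <- P[i, match(s$allele_1[i], lev)] + 0.5
      P[i, match(s$allele_2[i], lev)] <- P[i, match(s$allele_2[i], lev)] + 0.5
    }
    m <- sum(cnt)
    list(P = P, pbar = pbar, m = m, ok = ok)
  })
  locdat <- locdat[!vapply(locdat, is.null, TRUE)]
  if (length(locdat) == 0) abort("no polymorphic locus in this population")

  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (ld in locdat) {
    ok <- ld$ok
    both <- outer(ok, ok, "&")
    if (estimator == "loiselle") {
      ctr <- sweep(ld$P, 2, ld$pbar)
      ctr[is.na(ctr)] <- 0
      corr <- sum(ld$pbar * (1 - ld$pbar)) / (ld$m - 1)
      num <- num + (ctr %*% t(ctr) + corr) * both
      den <- den + sum(ld$pbar * (1 - ld$pbar)) * both
    } else {
      A <- length(ld$pbar)
      Ps <- sweep(ld$P, 2, ld$pbar, "/")
      Ps[is.na(Ps)] <- 0
      num <- num + ((ld$P %*% t(Ps)) - 1) * both
      den <- den + (A - 1) * both
    }
  }
  K <- num / den
  K[den == 0] <- NA_real_
  dimnames(K) <- list(ids, ids)
  K
}

#' Effective number of migrants from mutation-scaled parameters
#'
#' Converts coalescent estimates of the mutation-scaled population size
#' \eqn{\Theta = 4 N_E \mu} and migration rate \eqn{M = m/\mu} into the
#' effective number of immigrants per generation,
#' \eqn{N_E m = M \Theta / 4}.
#'
#' @param theta Mutation-scaled population size of the receiving
#'   population, non-negative.
#' @param m_scaled Mutation-scaled migration rate M, non-negative.
#' @return `N_E m`, same length as the inputs.
#' @export
nem_from_theta_m <- function(theta, m_scaled) {
  if (any(theta < 0) || any(m_scaled < 0)) abort("theta and M must be non-negative")
  m_scaled * theta / 4
}

#' Historical effective size from the mutation-scaled population size
#'
#' \eqn{N_E = \Theta / (4 \mu)}. The default mutation rate is the
#' microsatellite per-locus per-generation rate 4.76e-3.
#'
#' @param theta Mutation-scaled population size, non-negative.
#' @param mu Mutation rate per locus per generation, positive.
#' @return Historical effective size.
#' @export
historical_ne <- function(theta, mu = 4.76e-3) {
  if (any(mu <= 0)) abort("mu must be positive")
  if (any(theta < 0)) abort("theta must be non-negative")
  theta / (4 * mu)
}
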