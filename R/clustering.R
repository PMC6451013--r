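#' Bayesian admixture clustering
#'
#' Gibbs sampler for the admixture model with independent allele
#' frequencies across clusters: the latent origin z of each allele copy is
#' sampled with \eqn{P(z = k) \propto q_{ik}\, p_{k,l,a}}; individual
#' membership vectors \eqn{q_i} are Dirichlet(\eqn{\alpha} + per-cluster
#' copy counts); cluster allele frequencies are Dirichlet(\eqn{\lambda} +
#' allele counts); \eqn{\alpha} is updated by a Metropolis step under a
#' Uniform(0, 10) prior when `alpha_mode = "infer"`. Missing calls
#' contribute nothing. Q and P are posterior means over post-burn-in sweeps.
#'
#' @param x A [geno_tbl()].
#' @param K Number of clusters (at most the number of individuals).
#' @param burnin,iters Burn-in sweeps and total sweeps (`iters >= burnin`).
#' @param seed Integer seed.
#' @param alpha_mode `"infer"` (default) or `"fixed"`.
#' @param alpha Initial (or fixed) Dirichlet membership parameter.
#' @param lambda Allele-frequency prior parameter.
#' @param alpha_sd Metropolis step size for alpha.
#' @return A `cluster_run` with elements `Q` (tibble: individual,
#'   population, q_1..q_K), `P`, `loglik` trace, `K`, `alpha`, and the run
#'   settings.
#' @export
run_admixture <- function(x, K, burnin = 5000, iters = 20000, seed = 1,
                          alpha_mode = c("infer", "fixed"), alpha = 1,
                          lambda = 1, alpha_sd = 0.05) {
  alpha_mode <- match.arg(alpha_mode)
  if (K < 1) abort("K must be at least 1")
  if (K > n_individuals(x)) abort("K cannot exceed the number of individuals")
  if (iters < burnin || burnin < 0) abort("need iters >= burnin >= 0")

  enc <- encode_alleles(x)
  res <- with_seed(seed, cpp_admixture_gibbs(
    enc$geno, enc$n_alleles, as.integer(K), lambda, alpha,
    alpha_mode == "infer", alpha_sd, as.integer(burnin), as.integer(iters)
  ))
  Q <- as_tibble(res$Q, .name_repair = ~ paste0("q_", seq_len(K)))
  Q <- dplyr::bind_cols(enc$key, Q)
  structure(
    list(
      Q = Q, P = res$P, loglik = as.numeric(res$loglik),
      alpha = as.numeric(res$alpha), K = K, burnin = burnin, iters = iters,
      seed = seed, loci = enc$loci, allele_levels = enc$levels
    ),
    class = "cluster_run"
  )
}

# integer-index the alleles of each locus; 0 = missing
encode_alleles <- function(x) {
  key <- dplyr::arrange(
    dplyr::distinct(x, .data$individual, .data$population),
    .data$population, .data$individual
  )
  loci <- sort(unique(x$locus))
  n <- nrow(key)
  geno <- matrix(0L, n, 2 * length(loci))
  levels <- vector("list", length(loci))
  for (j in seq_along(loci)) {
    s <- x[x$locus == loci[j], ]
    s <- s[match(key$individual, s$individual), ]
    lev <- sort(unique(stats::na.omit(c(s$allele_1, s$allele_2))))
    if (length(lev) == 0) lev <- 1L # wholly missing locus: placeholder level
    levels[[j]] <- lev
    a1 <- match(s$allele_1, lev)
    a2 <- match(s$allele_2, lev)
    a1[is.na(a1)] <- 0L
    a2[is.na(a2)] <- 0L
    geno[, 2 * j - 1] <- a1
    geno[, 2 * j] <- a2
  }
  list(
    geno = geno, n_alleles = vapply(levels, length, 1L),
    key = key, loci = loci, levels = levels
  )
}

#' @export
print.cluster_run <- function(x, ...) {
  cat(sprintf(
    "Admixture run: K = %d, %d individuals, %d loci, %d sweeps (%d burn-in)\n",
    x$K, nrow(x$Q), length(x$loci), x$iters, x$burnin
  ))
  cat(sprintf(
    "mean post-burn-in ln L = %.2f\n",
    mean(x$loglik[(x$burnin + 1):x$iters])
  ))
  invisible(x)
}

#' @rdname run_admixture
#' @param ... Unused.
#' @export
tidy.cluster_run <- function(x, ...) {
  tidyr::pivot_longer(x$Q, dplyr::starts_with("q_"),
    names_to = "cluster", values_to = "q", names_prefix = "q_"
  )
}

#' @rdname run_admixture
#' @export
glance.cluster_run <- function(x, ...) {
  keep <- x$loglik[(x$burnin + 1):x$iters]
  tibble(
    K = x$K, mean_loglik = mean(keep), sd_loglik = stats::sd(keep),
    mean_alpha = mean(x$alpha[(x$burnin + 1):x$iters]),
    iters = x$iters, burnin = x$burnin, seed = x$seed
  )
}

# mean post-burn-in log-likelihood of a run
run_loglik <- function(run) mean(run$loglik[(run$burnin + 1):run$iters])

#' Replicated clustering over a grid of K
#'
#' Runs [run_admixture()] `replicates` times for each K with per-run seeds
#' derived from `seed`.
#'
#' @inheritParams run_admixture
#' @param k_range Integer vector of K values.
#' @param replicates Runs per K (Evanno's delta-K needs at least 2).
#' @return A list of `cluster_run` objects.
#' @export
admixture_scan <- function(x, k_range = 1:6, replicates = 5, burnin = 5000,
                           iters = 20000, seed = 1, ...) {
  runs <- list()
  for (K in k_range) {
    for (r in seq_len(replicates)) {
      runs[[length(runs) + 1L]] <- run_admixture(
        x, K,
        burnin = burnin, iters = iters,
        seed = seed + 1000L * K + r, ...
      )
    }
  }
  runs
}

#' Evanno delta-K model choice
#'
#' Summarises replicate runs over a contiguous K grid: per K the mean and
#' standard deviation of the post-burn-in log-likelihood, and
#' \eqn{\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / sd\, L(K)}
#' (undefined at the grid edges; an sd of 0 is guarded by 1e-9). The best K
#' by each criterion is attached as attributes `k_delta` and `k_loglik`.
#'
#' @param runs A list of `cluster_run` objects (e.g. [admixture_scan()]).
#' @return A `k_selection` tibble with columns `K`, `n_runs`,
#'   `mean_loglik`, `sd_loglik`, `delta_k`.
#' @export
select_k <- function(runs) {
  ll <- tibble(
    K = vapply(runs, function(r) as.integer(r$K), 1L),
    loglik = vapply(runs, run_loglik, 1)
  )
  out <- dplyr::summarise(
    dplyr::group_by(ll, .data$K),
    n_runs = dplyr::n(),
    mean_loglik = mean(.data$loglik),
    sd_loglik = stats::sd(.data$loglik),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$K)
  out$delta_k <- NA_real_
  if (nrow(out) >= 3 && all(diff(out$K) == 1)) {
    for (i in 2:(nrow(out) - 1)) {
      if (out$n_runs[i] < 2) next
      d2 <- abs(out$mean_loglik[i + 1] - 2 * out$mean_loglik[i] + out$mean_loglik[i - 1])
      out$delta_k[i] <- d2 / max(out$sd_loglik[i], 1e-9)
    }
  }
  attr(out, "k_delta") <- if (any(!is.na(out$delta_k))) {
    out$K[which.max(out$delta_k)]
  } else {
    NA_integer_
  }
  attr(out, "k_loglik") <- out$K[which.max(out$mean_loglik)]
  class(out) <- c("k_selection", class(out))
  out
}

#' Align replicate runs across cluster-label permutations
#'
#' Replicate runs at the same K are identified only up to a permutation of
#' cluster labels. For K of at most 8, an exhaustive search over label
#' permutations maximises the membership similarity
#' \eqn{\sum_i Q^{ref}_i \cdot Q^{perm}_i} against the first run; the
#' permutation-aligned mean Q matrix is returned (CLUMPP-style full search).
#'
#' @param runs A list of `cluster_run` objects sharing K and individuals.
#' @return A tibble like the `Q` element of a run, averaged after alignment.
#' @export
align_runs <- function(runs) {
  K <- runs[[1]]$K
  if (!all(vapply(runs, function(r) as.integer(r$K), 1L) == K)) {
    abort("all runs must share the same K")
  }
  ids <- runs[[1]]$Q$individual
  if (!all(vapply(runs, function(r) identical(r$Q$individual, ids), TRUE))) {
    abort("all runs must share the same individuals")
  }
  if (K > 8) abort("exhaustive label alignment supports K <= 8")
  qcols <- paste0("q_", seq_len(K))
  ref <- as.matrix(runs[[1]]$Q[qcols])
  perms <- permutations_of(K)
  acc <- ref
  for (r in runs[-1]) {
    M <- as.matrix(r$Q[qcols])
    best <- NULL
    best_sim <- -Inf
    for (i in seq_len(nrow(perms))) {
      sim <- sum(ref * M[, perms[i, ], drop = FALSE])
      if (sim > best_sim) {
        best_sim <- sim
        best <- perms[i, ]
      }
    }
    acc <- acc + M[, best, drop = FALSE]
  }
  out <- runs[[1]]$Q
  out[qcols] <- acc / length(runs)
  out
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    ins <- cbind(sub[, seq_len(i - 1), drop = FALSE], k,
                 sub[, seq(i, k - 1)[seq_len(k - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

#' Count admixed individuals
#'
#' Individuals whose membership in their modal cluster falls below
#' `threshold` are counted as admixed.
#'
#' @param q A Q tibble (from a run or [align_runs()]).
#' @param threshold Modal-membership cutoff (default 0.9).
#' @return A tibble per population: `n`, `n_admixed`, `prop_admixed`.
#' @export
admixture_summary <- function(q, threshold = 0.9) {
  qm <- apply(as.matrix(q[grep("^q_", names(q))]), 1, max)
  dplyr::summarise(
    dplyr::group_by(tibble(population = q$population, qmax = qm), .data$population),
    n = dplyr::n(),
    n_admixed = sum(.data$qmax < threshold),
    prop_admixed = mean(.data$qmax < threshold),
    .groups = "drop"
  )
}
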