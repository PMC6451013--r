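#' Analysis of molecular variance (one level)
#'
#' Decomposes the total squared inter-allele distance into among- and
#' within-population variance components at the gene-copy level (two copies
#' per diploid individual), following the Excoffier sums-of-squares
#' decomposition with the standard \eqn{n_c} coefficient for unequal sample
#' sizes. With the `identity` metric the fixation index is F(ST); with the
#' `allele_size` metric (squared repeat-count difference) it is Slatkin's
#' R(ST). Significance is assessed by permuting whole individuals among
#' populations.
#'
#' @param x A [geno_tbl()] with at least 2 populations.
#' @param metric `"identity"` (distance 0/1) or `"allele_size"` (squared
#'   difference in repeat units).
#' @param reps Number of permutations, at least 100.
#' @param seed Integer seed.
#' @param motif_length Per-locus repeat motif length in the units of the
#'   allele codes (scalar recycled, or named by locus). The default 1 means
#'   codes are already repeat counts. Pass `NULL` to require explicit
#'   lengths; an error is raised if polymorphic codes are then found.
#' @return An `amova_result` with components table, fixation index and
#'   permutation p-value. See [tidy()] and [glance()] methods.
#' @examples
#' g <- sim_genotypes(sim_config(seed = 7))$genotypes
#' amova(g, reps = 99)
#' @export
amova <- function(x, metric = c("identity", "allele_size"), reps = 999,
                  seed = 1, motif_length = 1) {
  metric <- match.arg(metric)
  if (n_populations(x) < 2) abort("amova needs at least 2 populations")
  if (reps < 100) abort("reps must be at least 100")

  D <- copy_distance_matrix(x, metric, motif_length)
  key <- dplyr::arrange(
    dplyr::distinct(x, .data$individual, .data$population),
    .data$population, .data$individual
  )
  n_ind <- nrow(key)
  pop <- factor(key$population)
  P <- nlevels(pop)
  copy_pop <- rep(as.integer(pop), 2L) # copies stacked [allele_1; allele_2]

  comp <- amova_components(D, copy_pop, P)
  obs <- comp$fixation

  hits <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      perm <- sample.int(n_ind)
      f <- amova_components(D, rep(as.integer(pop)[perm], 2L), P)$fixation
      if (!is.na(f) && f >= obs - 1e-12) hits <- hits + 1L
    }
  })

  structure(
    list(
      components = comp$table, fixation = obs,
      index = if (metric == "identity") "F_ST" else "R_ST",
      metric = metric, p = perm_p(hits, reps), reps = reps
    ),
    class = "amova_result"
  )
}

# summed-over-loci squared distance matrix between gene copies,
# pairwise-available over loci (a missing call drops that locus for a pair)
copy_distance_matrix <- function(x, metric, motif_length) {
  key <- dplyr::arrange(
    dplyr::distinct(x, .data$individual, .data$population),
    .data$population, .data$individual
  )
  loci <- sort(unique(x$locus))
  if (metric == "allele_size") {
    if (is.null(motif_length)) {
      poly <- any(vapply(loci, function(l) {
        length(unique(stats::na.omit(c(
          x$allele_1[x$locus == l], x$allele_2[x$locus == l]
        )))) > 1
      }, TRUE))
      if (poly) abort("allele_size metric requires motif_length for polymorphic loci")
      motif_length <- 1
    }
    motif <- if (is.null(names(motif_length))) {
      setNames(rep(motif_length, length.out = length(loci)), loci)
    } else {
      ml <- motif_length[loci]
      if (any(is.na(ml))) abort("motif_length must name every locus")
      ml
    }
  }
  n <- nrow(key)
  D <- matrix(0, 2 * n, 2 * n)
  for (l in loci) {
    s <- x[x$locus == l, ]
    s <- s[match(key$individual, s$individual), ]
    v <- c(s$allele_1, s$allele_2)
    if (metric == "identity") {
      dl <- outer(v, v, "!=") * 1
    } else {
      u <- v / motif[[l]]
      dl <- outer(u, u, "-")^2
    }
    dl[is.na(dl)] <- 0
    D <- D + dl
  }
  D
}

amova_components <- function(D, copy_pop, P) {
  N <- length(copy_pop)
  n_p <- tabulate(copy_pop, nbins = P)
  ssd_t <- sum(D) / (2 * N)
  ssd_w <- 0
  for (p in seq_len(P)) {
    idx <- which(copy_pop == p)
    ssd_w <- ssd_w + sum(D[idx, idx]) / (2 * n_p[p])
  }
  ssd_a <- ssd_t - ssd_w
  df_a <- P - 1L
  df_w <- N - P
  ms_a <- ssd_a / df_a
  ms_w <- ssd_w / df_w
  n_c <- (N - sum(n_p^2) / N) / (P - 1)
  sigma_w <- ms_w
  sigma_a <- (ms_a - ms_w) / n_c
  tot <- sigma_a + sigma_w
  fixation <- if (tot > 0) sigma_a / tot else NA_real_
  pct_a <- max(sigma_a, 0)
  pct <- c(pct_a, sigma_w) / (pct_a + sigma_w) * 100
  tab <- tibble(
    source = c("Among populations", "Within populations", "Total"),
    df = c(df_a, df_w, df_a + df_w),
    ss = c(ssd_a, ssd_w, ssd_t),
    sigma2 = c(sigma_a, sigma_w, sigma_a + sigma_w),
    pct_variation = c(pct, 100)
  )
  list(table = tab, fixation = fixation)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("One-level AMOVA (", x$metric, " metric)\n", sep = "")
  print(x$components)
  cat(sprintf(
    "%s = %.4f, permutation p = %.4g (%d permutations)\n",
    x$index, x$fixation, x$p, x$reps
  ))
  invisible(x)
}

#' @rdname amova
#' @param x An `amova_result`.
#' @param ... Unused.
#' @export
tidy.amova_result <- function(x, ...) x$components

#' @rdname amova
#' @export
glance.amova_result <- function(x, ...) {
  tibble(
    index = x$index, fixation = x$fixation, p = x$p,
    df_among = x$components$df[1], df_within = x$components$df[2],
    reps = x$reps
  )
}

#' Pairwise population differentiation
#'
#' Applies [amova()] to every pair of populations.
#'
#' @inheritParams amova
#' @param holm If `TRUE`, adds sequential-Bonferroni decisions across pairs.
#' @param alpha Family-wise error rate for the Holm decisions.
#' @return A tibble with columns `pop_1`, `pop_2`, `index`, `fixation`, `p`
#'   (and `reject` when `holm = TRUE`).
#' @export
pairwise_differentiation <- function(x, metric = c("identity", "allele_size"),
                                     reps = 999, seed = 1, motif_length = 1,
                                     holm = FALSE, alpha = 0.05) {
  metric <- match.arg(metric)
  pops <- unique(x$population)
  pairs <- combn(pops, 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(j) {
    sub <- x[x$population %in% pairs[, j], ]
    a <- amova(sub, metric = metric, reps = reps, seed = seed + j,
               motif_length = motif_length)
    tibble(
      pop_1 = pairs[1, j], pop_2 = pairs[2, j],
      index = a$index, fixation = a$fixation, p = a$p
    )
  })
  out <- dplyr::bind_rows(out)
  if (isTRUE(holm)) out$reject <- holm_bonferroni(out$p, alpha = alpha)
  out
}
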