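#' Sequential Bonferroni (Holm) decisions
#'
#' Holm's step-down procedure: the ascending-sorted p-values are rejected
#' while \eqn{p_{(i)} \le \alpha / (m - i + 1)}; the first failure stops all
#' further rejections. Decisions are returned in input order. Computed via
#' [stats::p.adjust()] with `method = "holm"`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param alpha Family-wise error rate, in (0, 1).
#' @return Logical vector of reject decisions, same length and order as `p`.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.03), alpha = 0.05) # only 0.01 rejected
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(logical(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  p.adjust(p, method = "holm") <= alpha
}

# unbiased gene diversity (m/(m-1)) (1 - sum p^2) from a copy count table
unbiased_he <- function(counts) {
  m <- sum(counts)
  if (m < 2) return(NA_real_)
  m / (m - 1) * (1 - sum((counts / m)^2))
}

# per (population, locus) cell list: copies vector, n individuals, H_O, H_E
pop_locus_cells <- function(x) {
  cells <- dplyr::group_by(x, .data$population, .data$locus)
  dplyr::summarise(cells,
    n_typed = sum(!is.na(.data$allele_1)),
    n_het = sum(.data$allele_1 != .data$allele_2, na.rm = TRUE),
    copies = list(c(rbind(
      .data$allele_1[!is.na(.data$allele_1)],
      .data$allele_2[!is.na(.data$allele_2)]
    ))),
    .groups = "drop"
  )
}

#' Null-allele scan with the Brookfield 1 estimator
#'
#' For every population x locus cell the observed homozygote count is
#' compared with its Monte-Carlo Hardy-Weinberg expectation (genotypes
#' assembled by drawing allele pairs from the cell's allele frequencies).
#' A cell is flagged when the observed count exceeds the 97.5th percentile
#' of the simulated counts. The Brookfield 1 null-allele frequency
#' \eqn{r = (H_E - H_O) / (1 + H_E)} is reported, clamped to \[0, 1\].
#'
#' @param x A [geno_tbl()].
#' @param reps Monte-Carlo replicates, at least 100.
#' @param seed Integer seed.
#' @return A tibble with columns `population`, `locus`, `n_typed`,
#'   `hom_obs`, `hom_q975`, `null_flag`, `brookfield_r`, `h_obs`, `h_exp`.
#' @export
null_allele_scan <- function(x, reps = 1000, seed = 1) {
  if (reps < 100) abort("reps must be at least 100")
  cells <- pop_locus_cells(x)
  with_seed(seed, {
    out <- purrr::pmap(cells, function(population, locus, n_typed, n_het, copies) {
      if (n_typed == 0) {
        return(tibble(
          population = population, locus = locus, n_typed = 0L,
          hom_obs = NA_integer_, hom_q975 = NA_real_, null_flag = FALSE,
          brookfield_r = NA_real_, h_obs = NA_real_, h_exp = NA_real_
        ))
      }
      counts <- table(copies)
      he <- unbiased_he(as.numeric(counts))
      ho <- n_het / n_typed
      r <- if (is.na(he)) NA_real_ else min(max((he - ho) / (1 + he), 0), 1)
      sim <- cpp_hom_count_mc(as.numeric(counts) / sum(counts), n_typed, as.integer(reps))
      q975 <- as.numeric(quantile(sim, 0.975, type = 1))
      hom_obs <- n_typed - n_het
      tibble(
        population = population, locus = locus, n_typed = n_typed,
        hom_obs = hom_obs, hom_q975 = q975,
        null_flag = hom_obs > q975,
        brookfield_r = r, h_obs = ho, h_exp = he
      )
    })
  })
  dplyr::bind_rows(out)
}

#' Randomization test of pairwise linkage disequilibrium
#'
#' For every population and locus pair, a log-likelihood-ratio G statistic
#' is computed on the two-locus genotype contingency table, and its p-value
#' is the proportion of permutations (single-locus genotypes shuffled among
#' individuals within the population) with G at least as large as observed,
#' with the \eqn{p \ge 1/(reps+1)} floor convention. Locus pairs with a
#' monomorphic member carry no information and are reported with `p = 1`.
#'
#' @inheritParams null_allele_scan
#' @param reps Permutation replicates, at least 100.
#' @return A tibble with columns `population`, `locus_1`, `locus_2`, `n`,
#'   `g_stat`, `p`.
#' @export
ld_test <- function(x, reps = 1000, seed = 1) {
  if (reps < 100) abort("reps must be at least 100")
  loci <- sort(unique(x$locus))
  if (length(loci) < 2) abort("ld_test needs at least 2 loci")
  pairs <- combn(loci, 2)
  with_seed(seed, {
    out <- purrr::map(unique(x$population), function(pop) {
      sub <- x[x$population == pop, ]
      purrr::map(seq_len(ncol(pairs)), function(j) {
        l1 <- pairs[1, j]; l2 <- pairs[2, j]
        g1 <- geno_codes(sub, l1)
        g2 <- geno_codes(sub, l2)
        keep <- !is.na(g1) & !is.na(g2)
        g1 <- factor(g1[keep]); g2 <- factor(g2[keep])
        if (length(g1) < 2 || nlevels(g1) < 2 || nlevels(g2) < 2) {
          return(tibble(
            population = pop, locus_1 = l1, locus_2 = l2,
            n = length(g1), g_stat = NA_real_, p = 1
          ))
        }
        res <- cpp_ld_gtest_perm(
          as.integer(g1), as.integer(g2),
          nlevels(g1), nlevels(g2), as.integer(reps)
        )
        tibble(
          population = pop, locus_1 = l1, locus_2 = l2,
          n = length(g1), g_stat = res[1], p = res[2]
        )
      })
    })
  })
  dplyr::bind_rows(purrr::flatten(out))
}

# unordered single-locus genotype label per individual, NA when missing
geno_codes <- function(sub, locus) {
  s <- sub[sub$locus == locus, ]
  s <- s[match(unique(sub$individual), s$individual), ]
  ifelse(is.na(s$allele_1), NA_character_,
    paste(pmin(s$allele_1, s$allele_2), pmax(s$allele_1, s$allele_2), sep = "/")
  )
}

#' Genotype-data QC report
#'
#' Bundles the null-allele scan and the pairwise LD randomization test, with
#' sequential Bonferroni (Holm) decisions over the LD p-values.
#'
#' @inheritParams null_allele_scan
#' @param alpha Family-wise error rate for the Holm decisions.
#' @return A list with elements `null_alleles`, `ld` (with an `ld_holm`
#'   decision column), `alpha`.
#' @export
qc_report <- function(x, reps = 1000, seed = 1, alpha = 0.05) {
  nulls <- null_allele_scan(x, reps = reps, seed = seed)
  ld <- ld_test(x, reps = reps, seed = seed + 1)
  ld$ld_holm <- holm_bonferroni(ld$p, alpha = alpha)
  list(null_alleles = nulls, ld = ld, alpha = alpha)
}
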