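#' Per-population diversity statistics
#'
#' Computes, for each population, the number of individuals N, the mean
#' number of alleles per locus A, rarefied allelic richness A_R at a
#' standard number of gene copies g, observed heterozygosity H_O, unbiased
#' expected heterozygosity H_E (Nei 1978,
#' \eqn{H_E = m/(m-1)\,(1 - \sum \hat p^2)} per locus), the multilocus
#' Weir-Cockerham inbreeding coefficient F_IS, and the number of private
#' alleles A_P (alleles found in that population and no other). A final
#' `Mean` row holds plain across-population means.
#'
#' @param x A [geno_tbl()].
#' @param g Rarefaction size in gene copies, or `"auto"` (the smallest
#'   non-missing gene-copy count over population x locus cells, the FSTAT
#'   convention). Cells with fewer than `g` copies are excluded from A_R
#'   with a warning.
#' @param fis_omit Character vector of populations for which F_IS is
#'   reported as `NA` (e.g. a pooled group of isolated individuals that is
#'   not a mating population).
#' @param fis_p If `TRUE`, adds a permutation p-value for F_IS and a Holm
#'   decision column (see [hwe_test()]).
#' @param reps,seed,alpha Passed to [hwe_test()] when `fis_p = TRUE`.
#' @return A tibble with one row per population plus a `Mean` row and
#'   columns `population`, `n`, `a`, `a_r`, `h_obs`, `h_exp`, `fis`, `a_p`
#'   (and `fis_p`, `fis_holm` when requested).
#' @export
diversity_table <- function(x, g = "auto", fis_omit = NULL, fis_p = FALSE,
                            reps = 1000, seed = 1, alpha = 0.05) {
  cells <- pop_locus_cells(x)
  cells$m <- 2L * cells$n_typed
  if (identical(g, "auto")) {
    g <- min(cells$m[cells$m > 0])
  }
  g <- as.integer(g)
  if (any(cells$m > 0 & cells$m < g)) {
    warn(sprintf(
      "%d population x locus cell(s) have fewer than g = %d gene copies; excluded from A_R",
      sum(cells$m > 0 & cells$m < g), g
    ))
  }

  freqs <- allele_frequencies(x)
  pops <- unique(x$population)
  # private alleles: present in exactly one population (per locus x allele)
  priv <- dplyr::summarise(
    dplyr::group_by(freqs, .data$locus, .data$allele),
    population = if (dplyr::n() == 1) .data$population[1] else NA_character_,
    .groups = "drop"
  )
  priv_count <- table(factor(priv$population, levels = pops))

  per_pop <- purrr::map(pops, function(pop) {
    cc <- cells[cells$population == pop & cells$n_typed > 0, ]
    ho <- mean(cc$n_het / cc$n_typed)
    locus_stats <- purrr::pmap(cc, function(population, locus, n_typed, n_het, copies, m) {
      counts <- as.numeric(table(copies))
      ar <- if (m >= g) sum(1 - choose(m - counts, g) / choose(m, g)) else NA_real_
      c(a = length(counts), he = unbiased_he(counts), ar = ar)
    })
    ls <- do.call(rbind, locus_stats)
    fis <- if (pop %in% fis_omit) NA_real_ else fis_estimate_pop(x, pop)
    tibble(
      population = pop,
      n = n_individuals(x[x$population == pop, ]),
      a = mean(ls[, "a"]),
      a_r = mean(ls[, "ar"], na.rm = TRUE),
      h_obs = ho,
      h_exp = mean(ls[, "he"], na.rm = TRUE),
      fis = fis,
      a_p = as.integer(priv_count[pop])
    )
  })
  out <- dplyr::bind_rows(per_pop)
  if (isTRUE(fis_p)) {
    hw <- hwe_test(x, reps = reps, seed = seed, alpha = alpha)
    out$fis_p <- hw$p[match(out$population, hw$population)]
    out$fis_p[out$population %in% fis_omit] <- NA_real_
    out$fis_holm <- hw$reject[match(out$population, hw$population)]
    out$fis_holm[out$population %in% fis_omit] <- NA
  }
  mean_row <- dplyr::summarise(out, dplyr::across(
    dplyr::where(is.numeric), ~ mean(.x, na.rm = TRUE)
  ))
  mean_row$population <- "Mean"
  if ("fis_holm" %in% names(out)) mean_row$fis_holm <- NA
  dplyr::bind_rows(out, mean_row)
}

# copies per locus for one population, as a list of paired-copy vectors
locus_copy_list <- function(x, pop) {
  cc <- pop_locus_cells(x[x$population == pop, ])
  purrr::map(cc$copies[cc$n_typed > 0], as.integer)
}

fis_estimate_pop <- function(x, pop) {
  copies <- locus_copy_list(x, pop)
  if (length(copies) == 0) return(NA_real_)
  cpp_hwe_fis_perm(copies, 0L)[1]
}

#' Multilocus inbreeding coefficient
#'
#' Weir-Cockerham (1984) \eqn{\hat f}: the within-individual and
#' among-individual variance components are summed over loci and alleles
#' before taking the ratio. Populations with no polymorphic locus are
#' reported as `NA` (F_IS is undefined, not zero).
#'
#' @param x A [geno_tbl()].
#' @return A tibble with columns `population`, `fis`.
#' @export
fis_estimate <- function(x) {
  tibble(
    population = unique(x$population),
    fis = unname(vapply(unique(x$population), function(p) fis_estimate_pop(x, p), 0))
  )
}

#' Permutation test of Hardy-Weinberg equilibrium
#'
#' The null distribution of the multilocus F_IS is built by shuffling
#' allele copies among individuals independently within each locus of each
#' population; the two-sided p-value is the proportion of permutations with
#' \eqn{|F_{IS}^*| \ge |F_{IS}|} (floor \eqn{1/(reps+1)}). Decisions across
#' populations use sequential Bonferroni ([holm_bonferroni()]).
#' Monomorphic populations are reported with `p = 1`.
#'
#' @param x A [geno_tbl()].
#' @param reps Permutation replicates, at least 200.
#' @param seed Integer seed.
#' @param alpha Family-wise error rate for the Holm decisions.
#' @return A tibble with columns `population`, `fis`, `p`, `reject`.
#' @export
hwe_test <- function(x, reps = 1000, seed = 1, alpha = 0.05) {
  if (reps < 200) abort("reps must be at least 200")
  pops <- unique(x$population)
  with_seed(seed, {
    res <- purrr::map(pops, function(pop) {
      copies <- locus_copy_list(x, pop)
      if (length(copies) == 0) {
        return(tibble(population = pop, fis = NA_real_, p = 1))
      }
      r <- cpp_hwe_fis_perm(copies, as.integer(reps))
      tibble(population = pop, fis = r[1], p = r[2])
    })
  })
  out <- dplyr::bind_rows(res)
  out$reject <- holm_bonferroni(out$p, alpha = alpha)
  out
}
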