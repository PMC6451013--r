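#' Configure the forward-time population simulator
#'
#' Builds a validated simulation configuration for [sim_genotypes()].
#' The defaults emulate the sampling regime of a severely fragmented
#' Neotropical tree: three relict populations plus a pooled group of
#' isolated individuals (four demes), 11 microsatellite loci mutating
#' under a two-phase model at 4.76e-3 per locus per generation, partial
#' selfing, weak migration, and a recent census crash a few generations
#' before sampling, with 62 individuals sampled in total (20/22/13/7).
#'
#' @param census Named integer vector of pre-crash deme census sizes.
#' @param sample_sizes Named integer vector (same demes) of final-
#'   generation sample sizes, each at most the census at sampling time.
#' @param migration Row-stochastic deme x deme matrix: `migration[d, s]` is
#'   the probability that an offspring born in deme `d` has its parents in
#'   deme `s`. Default: 0.02 among the three populations, 0.005 with the
#'   isolated group.
#' @param selfing Selfing probability in \[0, 1\].
#' @param n_loci Number of unlinked loci.
#' @param mu Mutation rate per allele copy per transmission.
#' @param model Mutation model: `"iam"`, `"smm"` or `"tpm"`.
#' @param p_multi,p_geom TPM multi-step fraction and geometric step
#'   parameter (variance 30 at the default 1/6).
#' @param crash `NULL`, or `list(when =` generations before sampling,
#'   `size =` named crashed census vector`)`.
#' @param burnin Pre-crash generations, or `"auto"` (10 x max census).
#' @param founder_allele Founder repeat count (codes reflect at 2).
#' @param seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(census = c(SER = 50, CON = 50, ESM = 25, AFI = 40),
                       sample_sizes = c(SER = 20, CON = 22, ESM = 13, AFI = 7),
                       migration = NULL, selfing = 0.25, n_loci = 11,
                       mu = 4.76e-3, model = c("tpm", "iam", "smm"),
                       p_multi = 0.3, p_geom = 1 / 6,
                       crash = list(when = 5, size = c(SER = 20, CON = 22, ESM = 14, AFI = 10)),
                       burnin = "auto", founder_allele = 20, seed = 1) {
  model <- match.arg(model)
  D <- length(census)
  demes <- names(census) %||% paste0("pop", seq_len(D))
  if (is.null(migration)) {
    migration <- matrix(0.02, D, D)
    if (D >= 4) {
      migration[D, ] <- 0.005
      migration[, D] <- 0.005
    }
    diag(migration) <- 0
    diag(migration) <- 1 - rowSums(migration)
  }
  if (!isTRUE(all.equal(rowSums(migration), rep(1, D), tolerance = 1e-12))) {
    abort("migration rows must sum to 1")
  }
  if (any(migration < 0) || selfing < 0 || selfing > 1 || mu < 0 || mu > 1 ||
    p_multi < 0 || p_multi > 1) {
    abort("all rates must lie in [0, 1]")
  }
  if (!identical(sort(names(sample_sizes)), sort(demes))) {
    names(sample_sizes) <- demes
  }
  final_census <- if (is.null(crash)) census else crash$size[demes]
  if (any(sample_sizes[demes] > final_census)) {
    abort("sample sizes cannot exceed the census at sampling time")
  }
  if (identical(burnin, "auto")) burnin <- 10L * max(census)
  structure(
    list(
      census = setNames(as.integer(census), demes),
      sample_sizes = setNames(as.integer(sample_sizes[demes]), demes),
      migration = migration, selfing = selfing, n_loci = as.integer(n_loci),
      mu = mu, model = model, p_multi = p_multi, p_geom = p_geom,
      crash = crash, burnin = as.integer(burnin),
      founder_allele = as.integer(founder_allele), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate genotype datasets with full truth logging
#'
#' Discrete non-overlapping generations: each offspring draws its parents'
#' deme from the migration matrix, selfs with probability `selfing`, and
#' each transmitted allele mutates at rate `mu` under the configured model
#' (IAM: fresh allele code; SMM: one repeat up or down; TPM: single step
#' with probability `1 - p_multi`, else a geometric multi-step). Sampling
#' is without replacement in the final generation.
#'
#' @param config A [sim_config()].
#' @return A list: `genotypes` (a [geno_tbl()]) and `truth` (realized
#'   census trajectory, migrant counts, deme of each sampled individual,
#'   crash settings, and the config).
#' @export
sim_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  demes <- names(config$census)
  D <- length(demes)
  when <- if (is.null(config$crash)) 0L else as.integer(config$crash$when)
  n_gen <- config$burnin + when + 1L
  traj <- matrix(rep(config$census, each = n_gen), n_gen, D)
  if (when > 0) {
    for (g in (n_gen - when + 1L):n_gen) {
      traj[g, ] <- as.integer(config$crash$size[demes])
    }
  }
  mcode <- match(config$model, c("iam", "smm", "tpm")) - 1L
  res <- with_seed(config$seed, {
    raw <- cpp_forward_sim(
      traj, config$migration, config$selfing, config$n_loci, config$mu,
      mcode, config$p_multi, config$p_geom, config$founder_allele, 100000L
    )
    rows <- purrr::map(seq_len(D), function(d) {
      mat <- raw$demes[[d]]
      take <- sample.int(nrow(mat), config$sample_sizes[d])
      purrr::map(seq_along(take), function(i) {
        tibble(
          individual = sprintf("%s_%02d", demes[d], i),
          population = demes[d],
          locus = sprintf("L%02d", seq_len(config$n_loci)),
          allele_1 = mat[take[i], 2 * seq_len(config$n_loci) - 1],
          allele_2 = mat[take[i], 2 * seq_len(config$n_loci)]
        )
      })
    })
    list(
      geno = geno_tbl(dplyr::bind_rows(purrr::flatten(rows))),
      migrants = raw$migrants
    )
  })
  deme_of <- setNames(
    rep(demes, config$sample_sizes),
    unique(res$geno$individual)
  )
  list(
    genotypes = res$geno,
    truth = list(
      config = config,
      census_trajectory = `colnames<-`(traj, demes),
      migrants = `colnames<-`(res$migrants, demes),
      deme_of = deme_of,
      crash = config$crash
    )
  )
}

#' Inject null alleles into a genotype table
#'
#' Marks the allele whose frequency (over the whole dataset) is closest to
#' `freq` at each named locus as a null: genotypes carrying one null copy
#' are recorded as homozygous for the visible allele; null homozygotes
#' become missing.
#'
#' @param x A [geno_tbl()].
#' @param loci Locus names to affect.
#' @param freq Target null-allele frequency used to pick the allele.
#' @return A list: `genotypes` (masked [geno_tbl()]) and `null_alleles`
#'   (tibble of locus, allele code and realized frequency).
#' @export
inject_null_alleles <- function(x, loci, freq = 0.3) {
  freqs <- allele_frequencies(x)
  picked <- purrr::map(loci, function(l) {
    f <- dplyr::summarise(
      dplyr::group_by(freqs[freqs$locus == l, ], .data$allele),
      count = sum(.data$count), .groups = "drop"
    )
    f$freq <- f$count / sum(f$count)
    f <- f[order(abs(f$freq - freq)), ]
    tibble(locus = l, allele = f$allele[1], realized_freq = f$freq[1])
  })
  picked <- dplyr::bind_rows(picked)
  for (i in seq_len(nrow(picked))) {
    l <- picked$locus[i]
    a <- picked$allele[i]
    rows <- which(x$locus == l)
    a1 <- x$allele_1[rows]
    a2 <- x$allele_2[rows]
    both <- !is.na(a1) & a1 == a & a2 == a
    one1 <- !is.na(a1) & a1 == a & a2 != a
    one2 <- !is.na(a2) & a2 == a & a1 != a
    a1[one1] <- a2[one1]
    a2[one2] <- a1[one2]
    a1[both] <- NA_integer_
    a2[both] <- NA_integer_
    x$allele_1[rows] <- a1
    x$allele_2[rows] <- a2
  }
  list(genotypes = x, null_alleles = picked)
}

#' Synthetic occurrence records
#'
#' Draws `n` records from a Thomas-process-style clustered sampler: a
#' fraction `clustering` of the points scatter normally (sd `cluster_sd`
#' degrees) around uniform parent centres, the rest are uniform on the
#' extent; points are clipped to the extent. Collection years and locality
#' labels are attached. With `outlier = TRUE` the last record is placed in
#' the far north-eastern corner region and labelled `"outlier"` (a
#' synthetic stand-in for a doubtful peripheral record). The default
#' extent spans about ten degrees of latitude in south-eastern South
#' America.
#'
#' @param n Number of records.
#' @param extent `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @param clustering Fraction of clustered points, in \[0, 1\].
#' @param cluster_sd Scatter of clustered points around their centre, deg.
#' @param n_clusters Number of parent centres.
#' @param outlier Add the labelled outlier record (counts toward `n`).
#' @param seed Integer seed.
#' @return An `occ_tbl` of `n` records.
#' @export
make_occurrences <- function(n = 19, extent = c(-46.5, -40, -23.5, -13.5),
                             clustering = 0.6, cluster_sd = 0.4,
                             n_clusters = 4, outlier = FALSE, seed = 1) {
  if (n < 1) abort("n must be at least 1")
  with_seed(seed, {
    n_main <- n - as.integer(outlier)
    n_clust <- round(clustering * n_main)
    centres <- tibble(
      lon = runif(n_clusters, extent[1], extent[2]),
      lat = runif(n_clusters, extent[3], extent[4])
    )
    pick <- sample.int(n_clusters, n_clust, replace = TRUE)
    pts <- tibble(
      lon = c(
        pmin(pmax(centres$lon[pick] + rnorm(n_clust, 0, cluster_sd), extent[1]), extent[2]),
        runif(n_main - n_clust, extent[1], extent[2])
      ),
      lat = c(
        pmin(pmax(centres$lat[pick] + rnorm(n_clust, 0, cluster_sd), extent[3]), extent[4]),
        runif(n_main - n_clust, extent[3], extent[4])
      )
    )
    if (outlier) {
      pts <- dplyr::bind_rows(pts, tibble(
        lon = extent[2] + 0.15 * (extent[2] - extent[1]),
        lat = extent[4] + 0.25 * (extent[4] - extent[3])
      ))
    }
    occurrence_set(tibble(
      id = sprintf("rec_%02d", seq_len(n)),
      locality = if (outlier) {
        c(sprintf("site_%02d", seq_len(n - 1)), "outlier")
      } else {
        sprintf("site_%02d", seq_len(n))
      },
      date = as.character(sample(1950:2015, n, replace = TRUE)),
      lat = pts$lat, lon = pts$lon
    ))
  })
}

#' Synthetic environmental raster stacks
#'
#' Builds smooth gradient-plus-noise layers on a regular grid:
#' `value = base + dlon (lon - xmin) + dlat (lat - ymin) + N(0, noise_sd)`.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @param layers Named list of specs
#'   `list(base =, dlon =, dlat =, noise_sd =)` (missing fields 0).
#' @param nrow,ncol Grid dimensions.
#' @param seed Integer seed.
#' @return A [raster_stack()].
#' @export
make_rasters <- function(extent = c(-46.5, -40, -23.5, -13.5),
                         layers = list(
                           temp = list(base = 24, dlon = 0, dlat = -0.8, noise_sd = 0.3),
                           prec = list(base = 1200, dlon = 40, dlat = 0, noise_sd = 30)
                         ),
                         nrow = 60, ncol = 60, seed = 1) {
  with_seed(seed, {
    dx <- (extent[2] - extent[1]) / ncol
    dy <- (extent[4] - extent[3]) / nrow
    lon <- extent[1] + (seq_len(ncol) - 0.5) * dx
    lat <- extent[4] - (seq_len(nrow) - 0.5) * dy
    mats <- purrr::map(layers, function(sp) {
      base <- sp$base %||% 0
      dlon <- sp$dlon %||% 0
      dlat <- sp$dlat %||% 0
      noise <- sp$noise_sd %||% 0
      m <- base + outer(lat - extent[3], rep(1, ncol)) * dlat +
        outer(rep(1, nrow), lon - extent[1]) * dlon
      if (noise > 0) m <- m + matrix(rnorm(nrow * ncol, 0, noise), nrow, ncol)
      m
    })
    raster_stack(mats, extent)
  })
}

#' Sample presence points of a synthetic niche-limited species
#'
#' Draws `n` presence points uniformly from the raster cells whose layer
#' values all fall inside the given niche bounds — a synthetic species
#' whose true distribution is a climate envelope, for testing envelope
#' models against known truth.
#'
#' @param stack A [raster_stack()].
#' @param n Number of presence points.
#' @param bounds Named list of `c(lo, hi)` per layer (a subset of the
#'   stack's layers).
#' @param seed Integer seed.
#' @return A tibble of `lon`, `lat` cell-centre coordinates.
#' @export
make_niche_presences <- function(stack, n, bounds, seed = 1) {
  cells <- rs_cells(stack)
  vals <- rs_extract(stack, cells$lon, cells$lat)
  ok <- rep(TRUE, nrow(cells))
  for (l in names(bounds)) {
    if (!l %in% names(vals)) abort(paste0("no such layer: ", l))
    ok <- ok & !is.na(vals[[l]]) & vals[[l]] >= bounds[[l]][1] &
      vals[[l]] <= bounds[[l]][2]
  }
  if (sum(ok) < n) abort("niche bounds leave fewer cells than n")
  with_seed(seed, cells[sample(which(ok), n), c("lon", "lat")])
}

#' Shift raster layers (future-scenario variant)
#'
#' Applies additive per-layer shifts, producing a "future" stack on the
#' same grid.
#'
#' @param stack A [raster_stack()].
#' @param shifts Named numeric vector of additive shifts (unnamed layers
#'   are left unchanged).
#' @return The shifted [raster_stack()].
#' @export
shift_rasters <- function(stack, shifts) {
  for (l in names(shifts)) {
    if (!l %in% names(stack$layers)) abort(paste0("no such layer: ", l))
    stack$layers[[l]] <- stack$layers[[l]] + shifts[[l]]
  }
  stack
}
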