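#' Genotype tables
#'
#' A genotype table (`geno_tbl`) is a long tibble of diploid codominant
#' genotype calls with one row per individual x locus and the columns
#' `individual`, `population`, `locus`, `allele_1`, `allele_2`. Alleles are
#' strictly positive integer codes (fragment sizes in base pairs or repeat
#' units); a missing genotype has `NA` in both allele columns — half-missing
#' calls are not representable and are demoted to missing on construction,
#' with a warning.
#'
#' @param x A data frame with columns `individual`, `population`, `locus`,
#'   `allele_1`, `allele_2`. Rows absent for an individual x locus pair are
#'   filled in as missing calls.
#' @return A validated `geno_tbl` tibble with one row per individual x locus.
#' @examples
#' g <- geno_tbl(data.frame(
#'   individual = c("i1", "i1", "i2", "i2"),
#'   population = "P1",
#'   locus      = c("L1", "L2", "L1", "L2"),
#'   allele_1   = c(100L, 150L, 102L, 150L),
#'   allele_2   = c(102L, 150L, 102L, 154L)
#' ))
#' n_loci(g)
#' @export
geno_tbl <- function(x) {
  req <- c("individual", "population", "locus", "allele_1", "allele_2")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    abort(paste0("genotype table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  x <- as_tibble(x)[req]
  x$individual <- as.character(x$individual)
  x$population <- as.character(x$population)
  x$locus <- as.character(x$locus)
  x$allele_1 <- as.integer(x$allele_1)
  x$allele_2 <- as.integer(x$allele_2)

  half <- xor(is.na(x$allele_1), is.na(x$allele_2))
  if (any(half)) {
    warn(sprintf("%d half-missing genotype(s) demoted to missing", sum(half)))
    x$allele_1[half] <- NA_integer_
    x$allele_2[half] <- NA_integer_
  }
  bad <- !is.na(x$allele_1) & (x$allele_1 <= 0L | x$allele_2 <= 0L)
  if (any(bad)) abort("allele codes must be strictly positive integers")

  popmap <- dplyr::distinct(x, .data$individual, .data$population)
  if (anyDuplicated(popmap$individual) > 0) {
    abort("each individual must belong to exactly one population")
  }
  if (nrow(popmap) < 2) abort("need at least 2 individuals")

  # complete the individual x locus grid with explicit missing calls
  grid <- tidyr::expand_grid(popmap, locus = unique(x$locus))
  x <- dplyr::left_join(grid, x, by = c("individual", "population", "locus"))
  x <- dplyr::arrange(x, .data$population, .data$individual, .data$locus)
  class(x) <- c("geno_tbl", class(x))
  x
}

#' @rdname geno_tbl
#' @export
n_loci <- function(x) length(unique(x$locus))

#' @rdname geno_tbl
#' @export
n_populations <- function(x) length(unique(x$population))

#' @rdname geno_tbl
#' @export
n_individuals <- function(x) length(unique(x$individual))

#' Read and write genotype files
#'
#' Supported dialects: GenePop (title line, locus list, `POP` blocks,
#' 2- or 3-digit allele codes, `0` = missing), STRUCTURE two-row-per-individual
#' matrices (`-9` or `0` = missing, first column individual id, second column
#' population), and the package's long CSV
#' (`individual,population,locus,allele_1,allele_2`, empty = missing).
#'
#' @param path File path.
#' @param format One of `"genepop"`, `"structure"`, `"csv"`.
#' @return `read_genotypes()` returns a [geno_tbl()]; `write_genotypes()`
#'   returns `path` invisibly.
#' @export
read_genotypes <- function(path, format = c("genepop", "structure", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  switch(format,
    genepop = read_genepop(path),
    structure = read_structure(path),
    csv = read_geno_csv(path)
  )
}

#' @rdname read_genotypes
#' @param x A [geno_tbl()].
#' @export
write_genotypes <- function(x, path, format = c("genepop", "structure", "csv")) {
  format <- match.arg(format)
  switch(format,
    genepop = write_genepop(x, path),
    structure = write_structure(x, path),
    csv = utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  )
  invisible(path)
}

read_geno_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  geno_tbl(x)
}

# GenePop codes concatenate the two alleles with a fixed digit width
split_genepop_code <- function(code, line) {
  nc <- nchar(code)
  if (!nc %in% c(4L, 6L)) {
    abort(sprintf("line %d: genotype code '%s' is not 4 or 6 digits", line, code))
  }
  w <- nc / 2L
  c(as.integer(substr(code, 1L, w)), as.integer(substr(code, w + 1L, nc)))
}

read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" | seq_along(lines) == 1L]
  if (length(lines) < 3) abort("genepop file too short")
  body <- lines[-1] # drop title
  pop_at <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_at) == 0) abort("genepop file has no POP line")
  # loci: either one per line before first POP, or one comma-separated line
  loci <- trimws(body[seq_len(pop_at[1] - 1)])
  if (length(loci) == 1 && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1]])
  }
  if (length(loci) == 0) abort("genepop file lists no loci")
  rows <- list()
  pop_idx <- 0L
  for (i in seq(pop_at[1], length(body))) {
    ln <- trimws(body[i])
    if (grepl("^pop$", ln, ignore.case = TRUE)) {
      pop_idx <- pop_idx + 1L
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) != 2) {
      abort(sprintf("line %d: expected 'id , genotypes'", i + 1L))
    }
    id <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(codes) != length(loci)) {
      abort(sprintf(
        "line %d: %d genotype codes for %d loci", i + 1L,
        length(codes), length(loci)
      ))
    }
    al <- vapply(codes, split_genepop_code, integer(2), line = i + 1L)
    rows[[length(rows) + 1L]] <- tibble(
      individual = id, population = sprintf("pop%d", pop_idx),
      locus = loci, allele_1 = al[1, ], allele_2 = al[2, ]
    )
  }
  x <- dplyr::bind_rows(rows)
  x$allele_1[x$allele_1 == 0L] <- NA_integer_
  x$allele_2[x$allele_2 == 0L] <- NA_integer_
  geno_tbl(x)
}

write_genepop <- function(x, path) {
  loci <- sort(unique(x$locus))
  width <- if (max(x$allele_1, x$allele_2, 0L, na.rm = TRUE) > 999L) 6L else 3L
  fmt <- function(a) {
    a[is.na(a)] <- 0L
    sprintf(paste0("%0", width, "d"), a)
  }
  out <- c("congenstatus genotype export", loci)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(x, code = paste0(fmt(.data$allele_1), fmt(.data$allele_2))),
    id_cols = c("individual", "population"),
    names_from = "locus", values_from = "code"
  )
  wide <- dplyr::arrange(wide, .data$population, .data$individual)
  for (p in unique(wide$population)) {
    out <- c(out, "POP")
    sub <- wide[wide$population == p, , drop = FALSE]
    out <- c(out, paste0(
      sub$individual, " , ",
      apply(as.matrix(sub[loci]), 1, paste, collapse = " ")
    ))
  }
  writeLines(out, path)
}

read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 3) abort("structure file too short")
  loci <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- lines[-1]
  if (length(body) %% 2 != 0) {
    abort("structure file needs two rows per individual (diploid only)")
  }
  rows <- list()
  for (i in seq(1, length(body), by = 2)) {
    r1 <- strsplit(trimws(body[i]), "\\s+")[[1]]
    r2 <- strsplit(trimws(body[i + 1]), "\\s+")[[1]]
    if (length(r1) != length(loci) + 2 || length(r2) != length(loci) + 2) {
      abort(sprintf("line %d: expected id, population, then %d alleles", i + 1L, length(loci)))
    }
    if (r1[1] != r2[1]) {
      abort(sprintf("line %d: the two rows of individual '%s' disagree", i + 2L, r1[1]))
    }
    rows[[length(rows) + 1L]] <- tibble(
      individual = r1[1], population = r1[2], locus = loci,
      allele_1 = as.integer(r1[-(1:2)]), allele_2 = as.integer(r2[-(1:2)])
    )
  }
  x <- dplyr::bind_rows(rows)
  for (col in c("allele_1", "allele_2")) {
    x[[col]][x[[col]] %in% c(0L, -9L)] <- NA_integer_
  }
  geno_tbl(x)
}

write_structure <- function(x, path) {
  loci <- sort(unique(x$locus))
  out <- paste(loci, collapse = " ")
  key <- dplyr::arrange(
    dplyr::distinct(x, .data$individual, .data$population),
    .data$population, .data$individual
  )
  for (i in seq_len(nrow(key))) {
    sub <- x[x$individual == key$individual[i], ]
    sub <- sub[match(loci, sub$locus), ]
    for (col in c("allele_1", "allele_2")) {
      a <- sub[[col]]
      a[is.na(a)] <- -9L
      out <- c(out, paste(c(key$individual[i], key$population[i], a), collapse = " "))
    }
  }
  writeLines(out, path)
}

#' Per-population allele frequencies
#'
#' Counts each allele over the non-missing calls of every population x locus
#' cell and divides by the number of gene copies `m` (twice the non-missing
#' individuals). Cells where every call is missing are absent from the result.
#'
#' @param x A [geno_tbl()].
#' @return A tibble with columns `population`, `locus`, `allele`, `count`,
#'   `freq`, `m`.
#' @export
allele_frequencies <- function(x) {
  long <- tidyr::pivot_longer(x, c("allele_1", "allele_2"),
    names_to = NULL, values_to = "allele"
  )
  long <- dplyr::filter(long, !is.na(.data$allele))
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$population, .data$locus, .data$allele),
    count = dplyr::n(), .groups = "drop_last"
  )
  out <- dplyr::mutate(out,
    m = sum(.data$count),
    freq = .data$count / .data$m
  )
  dplyr::arrange(
    dplyr::ungroup(out),
    .data$population, .data$locus, .data$allele
  )
}
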