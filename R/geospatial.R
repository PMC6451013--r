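#' Occurrence record tables
#'
#' An occurrence set is a tibble of georeferenced records with columns
#' `id`, `locality`, `date`, `lat`, `lon`. Dates may be ISO-8601 strings,
#' bare years, or `NA`; coordinates are decimal degrees (WGS84).
#'
#' @param x A data frame with the columns above (`locality` and `date`
#'   optional; missing ones are filled with the id / `NA`).
#' @return A validated `occ_tbl` tibble.
#' @export
occurrence_set <- function(x) {
  x <- as_tibble(x)
  if (!all(c("id", "lat", "lon") %in% names(x))) {
    abort("occurrence records need at least id, lat, lon")
  }
  if (!"locality" %in% names(x)) x$locality <- as.character(x$id)
  if (!"date" %in% names(x)) x$date <- NA_character_
  x <- x[c("id", "locality", "date", "lat", "lon")]
  x$id <- as.character(x$id)
  x$locality <- as.character(x$locality)
  x$date <- as.character(x$date)
  if (anyDuplicated(x$id) > 0) abort("record ids must be unique")
  if (any(is.na(x$lat)) || any(abs(x$lat) > 90)) abort("latitudes must lie in [-90, 90]")
  if (any(is.na(x$lon)) || any(abs(x$lon) > 180)) abort("longitudes must lie in [-180, 180]")
  class(x) <- c("occ_tbl", class(x))
  x
}

#' Read occurrence records from CSV
#'
#' @param path CSV file with columns id, locality, date, lat, lon (extra
#'   columns ignored; alternative column names can be mapped).
#' @param col_map Optional named character vector mapping the standard
#'   names to the file's column names, e.g.
#'   `c(lat = "latitude", lon = "longitude")`.
#' @return An `occ_tbl`.
#' @export
read_occurrences <- function(path, col_map = NULL) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      names(x)[names(x) == col_map[[std]]] <- std
    }
  }
  occurrence_set(x)
}

# parse a date string (ISO date or bare year) to a sortable numeric
parse_occ_date <- function(d) {
  out <- rep(NA_real_, length(d))
  full <- grepl("^\\d{4}-\\d{2}-\\d{2}$", d)
  if (any(full)) out[full] <- as.numeric(as.Date(d[full]))
  yr <- !full & grepl("^\\d{4}$", d)
  if (any(yr)) out[yr] <- as.numeric(as.Date(paste0(d[yr], "-01-01")))
  out
}

#' Deduplicate occurrence records by locality
#'
#' Keeps one record per locality label: the most recent by date. Undated
#' records lose ties to dated ones; exact date ties are broken by the
#' lexicographically smallest id. Output preserves the input row order of
#' the retained records.
#'
#' @param x An `occ_tbl` ([occurrence_set()]).
#' @return The filtered `occ_tbl`.
#' @export
dedupe_records <- function(x) {
  when <- parse_occ_date(x$date)
  when[is.na(when)] <- -Inf
  keep <- logical(nrow(x))
  for (loc in unique(x$locality)) {
    idx <- which(x$locality == loc)
    best <- idx[order(-when[idx], x$id[idx])][1]
    keep[best] <- TRUE
  }
  x[keep, ]
}

# world cylindrical equal-area projection (WGS84 authalic sphere), km
# standard parallel 0; areas are independent of the standard parallel
.r_authalic <- 6371.0072
cea_project <- function(lon, lat, lon0 = 0) {
  list(
    x = .r_authalic * (lon - lon0) * pi / 180,
    y = .r_authalic * sin(lat * pi / 180)
  )
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Extent of occurrence (minimum convex polygon)
#'
#' Projects the records to a cylindrical equal-area plane centred on their
#' mean longitude, takes the convex hull, and returns its area in km^2.
#' Degenerate inputs (fewer than 3 distinct points, or collinear points)
#' have area 0; the IUCN adjustment EOO >= AOO is applied downstream by
#' [assess_range()].
#'
#' @param x An `occ_tbl` with at least 1 record.
#' @return A list with `area_km2` and `hull` (tibble of hull vertices
#'   `lon`, `lat` in counter-clockwise order).
#' @export
eoo_area <- function(x) {
  if (nrow(x) < 1) abort("eoo_area needs at least 1 record")
  pr <- cea_project(x$lon, x$lat, lon0 = mean(x$lon))
  pts <- unique(cbind(pr$x, pr$y))
  if (nrow(pts) < 3) {
    return(list(area_km2 = 0, hull = tibble(lon = x$lon, lat = x$lat)))
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  area <- shoelace_area(pts[h, 1], pts[h, 2])
  keep <- match(
    paste(pts[h, 1], pts[h, 2]),
    paste(pr$x, pr$y)
  )
  list(area_km2 = area, hull = tibble(lon = x$lon[keep], lat = x$lat[keep]))
}

#' Area of occupancy on a reference grid
#'
#' Snaps the equal-area-projected records to a square grid of
#' `cell_km`-wide cells (IUCN reference scale 2 km, cell area 4 km^2) and
#' returns occupied-cell count x cell area. The grid origin defaults to
#' the projection origin; `origin_offset` shifts it, and `scan = TRUE`
#' additionally reports the min/max AOO over a 3 x 3 sub-cell offset scan
#' (grid-origin sensitivity).
#'
#' @param x An `occ_tbl`.
#' @param cell_km Cell width in km (default 2).
#' @param origin_offset Grid origin shift `c(dx, dy)` in km.
#' @param scan If `TRUE`, adds `aoo_min`/`aoo_max` over origin offsets.
#' @return A list with `area_km2`, `n_cells`, `cells` (tibble of occupied
#'   cell indices), and optionally `aoo_min`, `aoo_max`.
#' @export
aoo_area <- function(x, cell_km = 2, origin_offset = c(0, 0), scan = FALSE) {
  if (nrow(x) < 1) abort("aoo_area needs at least 1 record")
  pr <- cea_project(x$lon, x$lat, lon0 = 0)
  occupied <- function(dx, dy) {
    unique(tibble(
      ix = floor((pr$x - dx) / cell_km),
      iy = floor((pr$y - dy) / cell_km)
    ))
  }
  cells <- occupied(origin_offset[1], origin_offset[2])
  out <- list(
    area_km2 = nrow(cells) * cell_km^2,
    n_cells = nrow(cells),
    cells = cells,
    cell_km = cell_km
  )
  if (isTRUE(scan)) {
    grid <- expand.grid(
      dx = origin_offset[1] + cell_km * (0:2) / 3,
      dy = origin_offset[2] + cell_km * (0:2) / 3
    )
    counts <- purrr::map2_int(grid$dx, grid$dy, function(dx, dy) nrow(occupied(dx, dy)))
    out$aoo_min <- min(counts) * cell_km^2
    out$aoo_max <- max(counts) * cell_km^2
  }
  out
}

iucn_cat <- function(area, thresholds) {
  # thresholds ascending: CR, EN, VU bounds (strict "<")
  if (area < thresholds[1]) "CR" else if (area < thresholds[2]) "EN" else if (area < thresholds[3]) "VU" else "LC/NT"
}

#' IUCN criterion-B categorisation
#'
#' Applies the criterion-B area thresholds: extent of occurrence (B1)
#' CR < 100, EN < 5 000, VU < 20 000 km^2; area of occupancy (B2) CR < 10,
#' EN < 500, VU < 2 000 km^2. The subconditions (severe fragmentation,
#' continuing decline) are user-declared flags, not computed; the final
#' B2-based category equals the AOO-axis category when at least two
#' subconditions are met, otherwise `LC/NT`.
#'
#' @param eoo_km2,aoo_km2 Areas in km^2, non-negative.
#' @param fragmented,declining Subcondition flags.
#' @return A one-row tibble: `eoo_km2`, `aoo_km2`, `eoo_category`,
#'   `aoo_category`, `fragmented`, `declining`, `category`.
#' @examples
#' iucn_criterion_b(263905, 76, fragmented = TRUE, declining = TRUE)
#' @export
iucn_criterion_b <- function(eoo_km2, aoo_km2, fragmented = FALSE,
                             declining = FALSE) {
  if (eoo_km2 < 0 || aoo_km2 < 0) abort("areas must be non-negative")
  tibble(
    eoo_km2 = eoo_km2, aoo_km2 = aoo_km2,
    eoo_category = iucn_cat(eoo_km2, c(100, 5000, 20000)),
    aoo_category = iucn_cat(aoo_km2, c(10, 500, 2000)),
    fragmented = fragmented, declining = declining,
    category = if (fragmented && declining) {
      iucn_cat(aoo_km2, c(10, 500, 2000))
    } else {
      "LC/NT"
    }
  )
}

#' Full geospatial red-list assessment
#'
#' Deduplicates the records, computes EOO and AOO, applies the degenerate-
#' hull adjustment EOO := max(EOO, AOO), and categorises under IUCN
#' criterion B.
#'
#' @param x An `occ_tbl`.
#' @param cell_km AOO cell width in km.
#' @param fragmented,declining Criterion-B subcondition flags.
#' @param exclude_id Optional record ids to drop before assessment (e.g. a
#'   suspected misidentification).
#' @param dedupe Deduplicate by locality first (default `TRUE`).
#' @return An `iucn_assessment` list: `records`, `eoo`, `aoo`, and the
#'   [iucn_criterion_b()] `assessment` row.
#' @export
assess_range <- function(x, cell_km = 2, fragmented = FALSE,
                         declining = FALSE, exclude_id = NULL,
                         dedupe = TRUE) {
  if (!is.null(exclude_id)) x <- x[!x$id %in% exclude_id, ]
  if (isTRUE(dedupe)) x <- dedupe_records(x)
  eoo <- eoo_area(x)
  aoo <- aoo_area(x, cell_km = cell_km)
  eoo_adj <- max(eoo$area_km2, aoo$area_km2)
  structure(
    list(
      records = x, eoo = eoo, aoo = aoo,
      assessment = iucn_criterion_b(eoo_adj, aoo$area_km2,
        fragmented = fragmented, declining = declining
      )
    ),
    class = "iucn_assessment"
  )
}

#' @export
print.iucn_assessment <- function(x, ...) {
  a <- x$assessment
  cat(sprintf(
    "IUCN criterion B: EOO = %.0f km2 (%s), AOO = %.0f km2 (%s) -> %s\n",
    a$eoo_km2, a$eoo_category, a$aoo_km2, a$aoo_category, a$category
  ))
  invisible(x)
}

#' @rdname assess_range
#' @param ... Unused.
#' @export
glance.iucn_assessment <- function(x, ...) x$assessment
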