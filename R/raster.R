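#' Minimal raster stacks
#'
#' A `raster_stack` is a set of named layers on a shared regular
#' longitude/latitude grid: a list of numeric matrices (rows = latitude,
#' row 1 northernmost; columns = longitude) plus the extent
#' `c(xmin, xmax, ymin, ymax)` in decimal degrees. `NA` is NODATA and
#' propagates across layers.
#'
#' @param layers Named list of equal-dimension numeric matrices.
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)`.
#' @return A `raster_stack`.
#' @export
raster_stack <- function(layers, extent) {
  if (length(layers) < 1 || is.null(names(layers))) {
    abort("layers must be a non-empty named list")
  }
  dims <- unique(purrr::map(layers, dim))
  if (length(dims) != 1) abort("all layers must share dimensions")
  if (length(extent) != 4 || extent[1] >= extent[2] || extent[3] >= extent[4]) {
    abort("extent must be c(xmin, xmax, ymin, ymax)")
  }
  # NODATA propagates: a cell missing in any layer is missing in all
  na_mask <- Reduce(`|`, purrr::map(layers, is.na))
  layers <- purrr::map(layers, function(m) {
    m[na_mask] <- NA_real_
    m
  })
  structure(
    list(layers = layers, extent = as.numeric(extent),
         nrow = dims[[1]][1], ncol = dims[[1]][2]),
    class = "raster_stack"
  )
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf(
    "raster_stack: %d layer(s) [%s], %d x %d cells, extent [%g, %g] x [%g, %g]\n",
    length(x$layers), paste(names(x$layers), collapse = ", "),
    x$nrow, x$ncol, x$extent[1], x$extent[2], x$extent[3], x$extent[4]
  ))
  invisible(x)
}

# cell centre coordinates as a tibble (row-major, row 1 = north)
rs_cells <- function(stack) {
  dx <- (stack$extent[2] - stack$extent[1]) / stack$ncol
  dy <- (stack$extent[4] - stack$extent[3]) / stack$nrow
  tibble(
    row = rep(seq_len(stack$nrow), each = stack$ncol),
    col = rep(seq_len(stack$ncol), times = stack$nrow),
    lon = stack$extent[1] + (rep(seq_len(stack$ncol), times = stack$nrow) - 0.5) * dx,
    lat = stack$extent[4] - (rep(seq_len(stack$nrow), each = stack$ncol) - 0.5) * dy
  )
}

# row/col index of the cell containing each point (NA outside the extent)
rs_cell_of <- function(stack, lon, lat) {
  dx <- (stack$extent[2] - stack$extent[1]) / stack$ncol
  dy <- (stack$extent[4] - stack$extent[3]) / stack$nrow
  col <- floor((lon - stack$extent[1]) / dx) + 1
  row <- floor((stack$extent[4] - lat) / dy) + 1
  bad <- col < 1 | col > stack$ncol | row < 1 | row > stack$nrow
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble(row = as.integer(row), col = as.integer(col))
}

#' Extract layer values at point locations
#'
#' @param stack A [raster_stack()].
#' @param lon,lat Coordinate vectors in decimal degrees.
#' @return A tibble with one column per layer (NA outside the extent or on
#'   NODATA cells).
#' @export
rs_extract <- function(stack, lon, lat) {
  idx <- rs_cell_of(stack, lon, lat)
  out <- purrr::map(stack$layers, function(m) {
    v <- rep(NA_real_, nrow(idx))
    ok <- !is.na(idx$row)
    v[ok] <- m[cbind(idx$row[ok], idx$col[ok])]
    v
  })
  as_tibble(out)
}

# per-cell area (km^2) of each raster row under the equal-area projection
rs_cell_area_km2 <- function(stack) {
  dx <- (stack$extent[2] - stack$extent[1]) / stack$ncol
  dy <- (stack$extent[4] - stack$extent[3]) / stack$nrow
  lat_top <- stack$extent[4] - (seq_len(stack$nrow) - 1) * dy
  lat_bot <- lat_top - dy
  width <- .r_authalic * dx * pi / 180
  height <- .r_authalic * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
  width * height # one value per row
}

# total area of TRUE/1 cells of a logical/numeric matrix on this grid
suitable_area_km2 <- function(stack, m) {
  per_row <- rs_cell_area_km2(stack)
  sum(rowSums(m > 0.5, na.rm = TRUE) * per_row)
}
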