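#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Membership bar plot for admixture results
#'
#' STRUCTURE-style stacked bar chart of per-individual membership
#' coefficients, faceted by population.
#'
#' @param q A Q tibble (from [run_admixture()]'s `Q` element or
#'   [align_runs()]).
#' @return A ggplot object.
#' @export
plot_membership <- function(q) {
  long <- tidyr::pivot_longer(q, dplyr::starts_with("q_"),
    names_to = "cluster", values_to = "membership", names_prefix = "q_"
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$individual, y = .data$membership, fill = .data$cluster
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~population, scales = "free_x", space = "free_x") +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "membership (Q)", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6),
      panel.spacing = ggplot2::unit(0.1, "lines")
    )
}

#' @rdname select_k
#' @param object A `k_selection` tibble.
#' @param ... Unused.
#' @export
autoplot.k_selection <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$K, y = .data$delta_k)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' @rdname assess_range
#' @param object An `iucn_assessment`.
#' @export
autoplot.iucn_assessment <- function(object, ...) {
  hull <- object$eoo$hull
  ggplot2::ggplot(object$records, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_polygon(
      data = hull, fill = "steelblue", alpha = 0.2, colour = "steelblue"
    ) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(
      x = "longitude", y = "latitude",
      title = sprintf(
        "EOO %.0f km2 (%s), AOO %.0f km2 (%s)",
        object$assessment$eoo_km2, object$assessment$eoo_category,
        object$assessment$aoo_km2, object$assessment$aoo_category
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a raster layer or suitability surface
#'
#' @param stack A [raster_stack()] providing the grid.
#' @param values A matrix on the stack's grid (e.g. an ensemble consensus)
#'   or a layer name.
#' @return A ggplot object.
#' @export
plot_raster <- function(stack, values = names(stack$layers)[1]) {
  m <- if (is.character(values)) stack$layers[[values]] else values
  cells <- rs_cells(stack)
  cells$value <- as.vector(t(m))
  ggplot2::ggplot(cells, ggplot2::aes(
    x = .data$lon, y = .data$lat, fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::coord_quickmap() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}
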