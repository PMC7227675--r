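raster_tibble <- function(values, grid) {
  xy <- cell_centroids(grid, seq_len(n_cells(grid)))
  dplyr::mutate(xy, value = mat_to_cells(values))
}

#' Plot a landscape's covariates
#'
#' @param object A `garp_landscape`.
#' @param ... Unused.
#' @return A ggplot: one facet per covariate.
#' @method autoplot garp_landscape
#' @export
autoplot.garp_landscape <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            cols = -c("cell", "x", "y"),
                            names_to = "covariate", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude (deg)", y = "latitude (deg)", fill = NULL)
}

#' Plot a species' probability surface and presences
#'
#' @param object A `garp_species`.
#' @param grid The landscape [grid_spec()].
#' @param ... Unused.
#' @return A ggplot of the occurrence-probability surface with presence
#'   points overlaid.
#' @method autoplot garp_species
#' @export
autoplot.garp_species <- function(object, grid, ...) {
  df <- raster_tibble(object$probability, grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(data = object$presences, size = 0.6, colour = "black") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude (deg)", y = "latitude (deg)",
                  fill = "P(occurrence)")
}

#' Plot the agreement raster of a best subset
#'
#' @param object A `garp_best_subset`.
#' @param ... Unused.
#' @return A ggplot of model agreement (0..n_best votes for presence).
#' @method autoplot garp_best_subset
#' @export
autoplot.garp_best_subset <- function(object, ...) {
  df <- raster_tibble(object$agreement, object$grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, object$n_best)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude (deg)", y = "latitude (deg)",
                  fill = "agreement")
}

#' Bar plot of scaled median ranges
#'
#' Scaled median range per covariate (narrow bars = covariates the model
#' constrains tightly, hence influential), annotated with the raw median
#' range in covariate units and coloured by selection.
#'
#' @param object A `ui_contribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ui_contribution
#' @export
autoplot.ui_contribution <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$ui)
  df$covariate <- factor(df$covariate, levels = rev(df$covariate))
  ggplot2::ggplot(df, ggplot2::aes(.data$scaled_median_range, .data$covariate,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$median_range, 3)),
                       hjust = -0.1, size = 3) +
    ggplot2::scale_x_continuous(limits = c(0, 1.15)) +
    ggplot2::labs(x = "scaled median range", y = NULL, fill = "selected")
}

#' Observed versus expected recovery counts
#'
#' @param object A `ui_validation`.
#' @param ... Unused.
#' @return A ggplot of observed and null-expected counts of species per
#'   number of correctly identified variables, faceted by scenario.
#' @method autoplot ui_validation
#' @export
autoplot.ui_validation <- function(object, ...) {
  df <- tidyr::pivot_longer(object$tallies,
                            cols = c("observed", "expected"),
                            names_to = "kind", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$r), .data$count,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "correctly identified variables (r)", y = "species",
                  fill = NULL)
}
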