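#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a reconstructed track
#'
#' Mean track coloured by season, with the release point marked.
#'
#' @param object A `tt_geofit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tt_geofit <- function(object, ...) {
  tr <- object$track
  ggplot2::ggplot(tr, ggplot2::aes(.data$lon_mean, .data$lat_mean)) +
    ggplot2::geom_path(ggplot2::aes(colour = season_of(.data$time))) +
    ggplot2::geom_point(data = tr[1, ], shape = 17, size = 3) +
    ggplot2::labs(x = "Longitude", y = "Latitude", colour = "Season",
                  title = paste("Mean track, tag", object$tag_id)) +
    ggplot2::coord_quickmap() +
    ggplot2::theme_minimal()
}

#' Plot monthly listening effort
#'
#' @param effort Output of [listening_effort()].
#' @return A ggplot bar chart of cumulative listening days per month.
#' @export
plot_listening_effort <- function(effort) {
  ggplot2::ggplot(effort,
                  ggplot2::aes(.data$month, .data$listening_days)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Listening days") +
    ggplot2::theme_minimal()
}

#' Plot residency against fish length
#'
#' Number of residency periods versus total length, coloured by
#' maturity.
#'
#' @param per_fish The `per_fish` element of [residency_summary()].
#' @return A ggplot.
#' @export
plot_residency <- function(per_fish) {
  ggplot2::ggplot(per_fish,
                  ggplot2::aes(.data$total_length_mm, .data$n_periods,
                               colour = .data$maturity)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Total length (mm)", y = "Residency periods",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one posterior slice as a probability map
#'
#' @param stack A `tt_stack` (posterior or likelihood).
#' @param slice Slice index.
#' @return A ggplot raster of the slice.
#' @export
plot_posterior_slice <- function(stack, slice = 1) {
  g <- stack$grid
  df <- tidyr::expand_grid(lon = g$lon, lat = g$lat)
  df$value <- as.vector(stack$values[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "P",
                  title = fmt_utc(stack$times[slice])) +
    ggplot2::theme_minimal()
}
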