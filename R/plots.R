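#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_tidy <- function(r, value_name = "value") {
  nr <- nrow(r$values); nc <- ncol(r$values)
  out <- tibble::tibble(
    lon = rep(r$west + (seq_len(nc) - 0.5) * r$dx, each = nr),
    lat = rep(r$north - (seq_len(nr) - 0.5) * r$dy, times = nc),
    value = as.vector(r$values))
  names(out)[3L] <- value_name
  out
}

#' Plot a raster layer
#'
#' @param x An `eco_raster`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eco_raster <- function(x, ...) {
  df <- raster_tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}

#' Plot a suitability surface
#'
#' Shows the bounded 0-0.999 suitability index; the binary suitable
#' mask is `autoplot(surface$mask)`.
#'
#' @param x A completed `eco_surface`.
#' @param layer `"suitability"`, `"distance"` or `"mask"`.
#' @param ... Unused.
#' @export
autoplot.eco_surface <- function(x, layer = c("suitability", "distance",
                                              "mask"), ...) {
  layer <- match.arg(layer)
  r <- x[[layer]]
  if (is.null(r)) stop(sprintf("surface has no '%s' layer yet", layer))
  autoplot(r) +
    ggplot2::labs(fill = layer,
                  title = sprintf("%s (%s)", x$species, layer))
}

#' Bar chart of jackknife variable contributions
#'
#' @param x An `eco_contrib` table.
#' @param ... Unused.
#' @export
autoplot.eco_contrib <- function(x, ...) {
  df <- dplyr::arrange(tibble::as_tibble(x), .data$contribution)
  df$variable <- factor(df$variable, levels = df$variable)
  ggplot2::ggplot(df, ggplot2::aes(.data$contribution, .data$variable)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Contribution to habitat suitability (%)",
                  y = NULL)
}

#' Bar chart of suitable area per region
#'
#' @param areas Tibble from [area_by_region()].
#' @param level Which hierarchy level to show (default continents).
#' @export
plot_area_table <- function(areas, level = "continent") {
  df <- dplyr::filter(areas, .data$level == !!level)
  ggplot2::ggplot(df, ggplot2::aes(.data$region, .data$area_1e5km2,
                                   fill = .data$species)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression("Suitable area (" * 10^5 ~ km^2 * ")"))
}

#' Plot an envelope profile's per-variable ranges
#'
#' @param x An `eco_profile`.
#' @param ... Unused.
#' @export
autoplot.eco_profile <- function(x, ...) {
  df <- x$ranges
  ggplot2::ggplot(df, ggplot2::aes(y = .data$variable)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$min, xend = .data$max,
                                       yend = .data$variable),
                          linewidth = 3, colour = "steelblue") +
    ggplot2::labs(title = x$species, x = "Suitable range (native units)",
                  y = NULL)
}
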