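## Mean Earth radius (IUGG), km.
EARTH_RADIUS_KM <- 6371.0088

#' Exact spherical area of grid cells in one row
#'
#' On a geographic grid the area of a cell depends only on its row:
#' A = R^2 * dlambda * (sin(phi_north) - sin(phi_south)) with
#' R = 6371.0088 km. This replaces any zone-local projected
#' measurement with an exact closed form on the sphere.
#'
#' @param row Integer row index (1 = northernmost); vectorized.
#' @param grid An `eco_raster` supplying the geotransform.
#' @return Cell area(s) in km².
#' @export
cell_area <- function(row, grid) {
  if (any(row < 1L | row > nrow(grid$values)))
    stop("row outside grid")
  phi_n <- (grid$north - (row - 1L) * grid$dy) * pi / 180
  phi_s <- (grid$north - row * grid$dy) * pi / 180
  EARTH_RADIUS_KM^2 * (grid$dx * pi / 180) * (sin(phi_n) - sin(phi_s))
}

#' Suitable area per administrative region
#'
#' Attributes every cell to the region containing its center
#' (point-in-polygon at the country level), sums exact spherical cell
#' areas over suitable cells, and aggregates country rows into their
#' parent continents. Suitable cell centers falling in no region
#' (ocean) are reported in an `"unassigned"` row.
#'
#' @param mask Binary suitable `eco_raster` (1 = suitable; `NA`
#'   treated as unsuitable).
#' @param regions An `eco_regions` object with country-level polygons
#'   carrying continent parents.
#' @param species Species label for the output rows.
#' @return A tibble with columns `species`, `region`, `level`,
#'   `area_km2`, `area_1e5km2`, including continent aggregates and a
#'   species total row (`level = "total"`).
#' @export
area_by_region <- function(mask, regions, species = "species") {
  suit <- which(!is.na(mask$values) & mask$values == 1, arr.ind = TRUE)
  empty_levels <- tibble::tibble(
    region = regions$name[regions$level == "country"],
    level = "country",
    parent = regions$parent[regions$level == "country"])
  if (nrow(suit) == 0L) {
    rows <- dplyr::mutate(empty_levels, area_km2 = 0)
  } else {
    ctr <- cell_center(mask, suit[, "row"], suit[, "col"])
    region <- region_lookup(regions, ctr$lon, ctr$lat, level = "country")
    areas <- cell_area(suit[, "row"], mask)
    rows <- tibble::tibble(region = ifelse(is.na(region), "unassigned", region),
                           area_km2 = areas)
    rows <- dplyr::summarise(dplyr::group_by(rows, .data$region),
                             area_km2 = sum(.data$area_km2), .groups = "drop")
    rows <- dplyr::left_join(
      rows,
      tibble::tibble(region = c(empty_levels$region, "unassigned"),
                     level = c(empty_levels$level, "unassigned"),
                     parent = c(empty_levels$parent, NA_character_)),
      by = "region")
    missing <- dplyr::anti_join(empty_levels, rows, by = "region")
    rows <- dplyr::bind_rows(rows, dplyr::mutate(missing, area_km2 = 0))
  }
  rows$level[is.na(rows$level)] <- "country"
  continents <- rows |>
    dplyr::filter(.data$level == "country", !is.na(.data$parent)) |>
    dplyr::group_by(region = .data$parent) |>
    dplyr::summarise(area_km2 = sum(.data$area_km2), .groups = "drop") |>
    dplyr::mutate(level = "continent")
  total <- tibble::tibble(region = "global", level = "total",
                          area_km2 = sum(rows$area_km2))
  out <- dplyr::bind_rows(
    dplyr::select(rows, "region", "level", "area_km2"),
    continents, total)
  out <- dplyr::mutate(out,
                       species = species,
                       area_1e5km2 = .data$area_km2 / 1e5,
                       .before = 1L)
  dplyr::arrange(out, factor(.data$level,
                             levels = c("country", "continent",
                                        "unassigned", "total")),
                 .data$region)
}

#' Write an area table as CSV
#'
#' @param areas Tibble from [area_by_region()].
#' @param path Output path.
#' @export
write_area_table <- function(areas, path) {
  utils::write.csv(areas, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
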