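#' Administrative region set
#'
#' Named polygons with a two-level hierarchy (continent -> country),
#' emulating a global administrative-areas database. Geometry is stored
#' as a list of two-column longitude/latitude matrices, one or more
#' rings per region (rings are closed on construction).
#'
#' @param name Character vector of region names (unique within a level).
#' @param level `"country"` or `"continent"` per region. Continents may
#'   be given implicitly through `parent` only; [area_by_region()]
#'   aggregates country rows by parent.
#' @param parent Parent region name (`NA` for top level).
#' @param geometry List of rings: each element a list of closed
#'   two-column matrices (lon, lat), or a single matrix.
#' @return An object of class `eco_regions` (a tibble).
#' @export
region_set <- function(name, level, parent, geometry) {
  stopifnot(length(name) == length(level),
            length(name) == length(parent),
            length(name) == length(geometry))
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) g <- list(g)
    lapply(g, close_ring)
  })
  for (lv in unique(level)) {
    nm <- name[level == lv]
    if (anyDuplicated(nm))
      stop(sprintf("duplicate region name within level '%s'", lv))
  }
  out <- tibble::tibble(name = as.character(name),
                        level = as.character(level),
                        parent = as.character(parent),
                        geometry = geometry)
  class(out) <- c("eco_regions", class(out))
  out
}

close_ring <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 2L, nrow(m) >= 3L)
  if (any(m[1L, ] != m[nrow(m), ])) m <- rbind(m, m[1L, ])
  m
}

#' Read regions from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon / MultiPolygon features with
#' `name`, `level` and `parent` properties.
#'
#' @param path GeoJSON file path.
#' @return An `eco_regions` object.
#' @export
read_geojson_regions <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  feats <- gj$features
  grab <- function(f, key) {
    v <- f$properties[[key]]
    if (is.null(v)) NA_character_ else as.character(v)
  }
  ring_to_matrix <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
  geom <- lapply(feats, function(f) {
    g <- f$geometry
    if (g$type == "Polygon") {
      lapply(g$coordinates, ring_to_matrix)
    } else if (g$type == "MultiPolygon") {
      unlist(lapply(g$coordinates, function(poly)
        lapply(poly, ring_to_matrix)), recursive = FALSE)
    } else stop(sprintf("unsupported geometry type '%s'", g$type))
  })
  region_set(
    name = vapply(feats, grab, character(1L), key = "name"),
    level = vapply(feats, grab, character(1L), key = "level"),
    parent = vapply(feats, grab, character(1L), key = "parent"),
    geometry = geom
  )
}

#' Write regions as GeoJSON
#'
#' @param regions An `eco_regions` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson_regions <- function(regions, path) {
  features <- purrr::pmap(
    list(regions$name, regions$level, regions$parent, regions$geometry),
    function(name, level, parent, geometry) {
      coords <- lapply(geometry, function(ring)
        lapply(seq_len(nrow(ring)), function(i) as.list(unname(ring[i, ]))))
      list(
        type = "Feature",
        properties = list(name = name, level = level, parent = parent),
        geometry = list(type = "Polygon", coordinates = coords)
      )
    }
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Locate points in regions
#'
#' Assigns each point to the first region (in table order) whose
#' polygon contains it, using even-odd ray crossing. Points in no
#' region get `NA` (typically ocean cells; area accounting reports them
#' as "unassigned").
#'
#' @param regions An `eco_regions` object.
#' @param lon,lat Point coordinate vectors (degrees).
#' @param level Restrict the lookup to one hierarchy level
#'   (default `"country"`).
#' @return Character vector of region names (`NA` where unmatched).
#' @export
region_lookup <- function(regions, lon, lat, level = "country") {
  rows <- which(regions$level == level)
  out <- rep(NA_character_, length(lon))
  pts <- cbind(lon, lat)
  for (i in rows) {
    todo <- is.na(out)
    if (!any(todo)) break
    bnd <- do.call(rbind, lapply(regions$geometry[[i]], function(r)
      rbind(r, c(NA, NA))))
    inside <- mgcv::in.out(bnd, pts[todo, , drop = FALSE])
    out[todo][inside] <- regions$name[i]
  }
  out
}
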