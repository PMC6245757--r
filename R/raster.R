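#' Gridded raster container
#'
#' A lightweight in-memory raster: a numeric matrix on a regular
#' geographic (longitude/latitude, WGS84) grid. Row 1 is the
#' northernmost row; columns run west to east. The geotransform is the
#' tuple (west, north, dx, dy) in decimal degrees, with `dx`, `dy` > 0.
#'
#' @param values Numeric matrix, row-major with row 1 = north.
#' @param west,north Coordinates of the grid's north-west corner (degrees).
#' @param dx,dy Cell width and height in degrees (both > 0).
#' @param nodata Sentinel for missing cells. Cells equal to `nodata` are
#'   converted to `NA` on construction; `NA` is the in-memory missing value.
#' @param crs Coordinate reference tag; only `"WGS84"` geographic grids
#'   are supported.
#' @return An object of class `eco_raster`.
#' @export
eco_raster <- function(values, west, north, dx, dy, nodata = -9999,
                       crs = "WGS84") {
  stopifnot(is.matrix(values), is.numeric(dx), is.numeric(dy))
  if (dx <= 0 || dy <= 0) stop("cell width and height must be positive")
  values[!is.na(values) & values == nodata] <- NA_real_
  structure(
    list(values = values, west = west, north = north,
         dx = dx, dy = dy, nodata = nodata, crs = crs),
    class = "eco_raster"
  )
}

#' @export
print.eco_raster <- function(x, ...) {
  cat(sprintf(
    "<eco_raster> %d x %d cells, %s\n  extent: lon [%g, %g], lat [%g, %g], cell %g x %g deg\n  values: [%g, %g], %d NA\n",
    nrow(x$values), ncol(x$values), x$crs,
    x$west, x$west + ncol(x$values) * x$dx,
    x$north - nrow(x$values) * x$dy, x$north,
    x$dx, x$dy,
    suppressWarnings(min(x$values, na.rm = TRUE)),
    suppressWarnings(max(x$values, na.rm = TRUE)),
    sum(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.eco_raster <- function(x) dim(x$values)

raster_south <- function(r) r$north - nrow(r$values) * r$dy
raster_east <- function(r) r$west + ncol(r$values) * r$dx

#' Map coordinates to raster cell indices
#'
#' Cell ownership follows the half-open convention: a point maps to
#' column `floor((lon - west)/dx) + 1` and row
#' `floor((north - lat)/dy) + 1`, so a point lying exactly on a shared
#' edge belongs to the cell to its south-east. Points outside the grid
#' extent (including the outer east and south edges) get `NA` indices.
#'
#' @param r An `eco_raster`.
#' @param lon,lat Coordinate vectors (degrees).
#' @return A tibble with columns `row`, `col` (`NA` when out of bounds).
#' @export
cell_index <- function(r, lon, lat) {
  col <- floor((lon - r$west) / r$dx) + 1L
  row <- floor((r$north - lat) / r$dy) + 1L
  bad <- col < 1L | col > ncol(r$values) | row < 1L | row > nrow(r$values)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Coordinates of cell centers
#'
#' @param r An `eco_raster`.
#' @param row,col Cell indices (1-based).
#' @return A tibble with `lon`, `lat` of each cell center.
#' @export
cell_center <- function(r, row, col) {
  tibble::tibble(
    lon = r$west + (col - 0.5) * r$dx,
    lat = r$north - (row - 0.5) * r$dy
  )
}

#' Multi-variable raster stack
#'
#' An ordered, named collection of co-registered `eco_raster` layers,
#' one per ecological factor. All layers must share shape, geotransform
#' (to 1e-9 degrees) and reference tag.
#'
#' @param ... Named `eco_raster` layers, or a single named list of them.
#' @return An object of class `eco_stack`.
#' @export
variable_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && !inherits(layers[[1L]], "eco_raster"))
    layers <- layers[[1L]]
  if (is.null(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named")
  if (anyDuplicated(names(layers)))
    stop("layer names must be unique")
  ref <- layers[[1L]]
  for (nm in names(layers)[-1L])
    check_aligned(ref, layers[[nm]], nm)
  structure(list(layers = layers), class = "eco_stack")
}

#' @export
print.eco_stack <- function(x, ...) {
  r <- x$layers[[1L]]
  cat(sprintf("<eco_stack> %d variables on a %d x %d grid: %s\n",
              length(x$layers), nrow(r$values), ncol(r$values),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.eco_stack <- function(x) names(x$layers)

check_aligned <- function(ref, r, name, tol = 1e-9) {
  if (!identical(dim(ref$values), dim(r$values)))
    stop(sprintf("layer '%s' has shape %dx%d, expected %dx%d", name,
                 nrow(r$values), ncol(r$values),
                 nrow(ref$values), ncol(ref$values)))
  gt <- c(ref$west - r$west, ref$north - r$north,
          ref$dx - r$dx, ref$dy - r$dy)
  if (any(abs(gt) > tol))
    stop(sprintf("layer '%s' geotransform differs from reference", name))
  if (!identical(ref$crs, r$crs))
    stop(sprintf("layer '%s' reference tag differs", name))
  invisible(TRUE)
}

#' Check co-registration of a stack and a raster
#'
#' Passes iff shapes and geotransforms agree to within 1e-9 degrees;
#' otherwise throws an error naming the offending layer.
#'
#' @param stack An `eco_stack`.
#' @param raster An `eco_raster` (e.g. the soil layer).
#' @param name Label used in error messages.
#' @return `TRUE`, invisibly, on success.
#' @export
align_check <- function(stack, raster, name = "raster") {
  check_aligned(stack$layers[[1L]], raster, name)
}

#' Read an ESRI ASCII grid
#'
#' Plain-text raster dialect: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by the
#' value matrix, north row first.
#'
#' @param path File path.
#' @param crs Reference tag to attach.
#' @return An `eco_raster`.
#' @export
read_ascii_grid <- function(path, crs = "WGS84") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[key]])) stop(sprintf("missing header field '%s'", key))
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("value count does not match header dimensions")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  eco_raster(m,
             west = hdr$xllcorner,
             north = hdr$yllcorner + hdr$nrows * hdr$cellsize,
             dx = hdr$cellsize, dy = hdr$cellsize,
             nodata = nodata, crs = crs)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]. Requires square cells (`dx == dy`),
#' a restriction of the format itself. `NA` cells are written as the
#' nodata sentinel. Values round-trip at full `%.9g` precision, beyond
#' float32.
#'
#' @param r An `eco_raster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path) {
  if (abs(r$dx - r$dy) > 1e-12)
    stop("ESRI ASCII grids require square cells")
  v <- r$values
  v[is.na(v)] <- r$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$west),
    sprintf("yllcorner %.10g", r$north - nrow(v) * r$dy),
    sprintf("cellsize %.10g", r$dx),
    sprintf("NODATA_value %.10g", r$nodata)
  )
  body <- apply(v, 1L, function(row) paste(sprintf("%.9g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a stack of ASCII grids
#'
#' @param paths Named character vector of file paths; names become
#'   variable names.
#' @return An `eco_stack`.
#' @export
read_stack <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("paths must be named by variable")
  variable_stack(lapply(paths, read_ascii_grid))
}

#' Extract climate values at occurrence points
#'
#' Maps every record to the cell containing it (half-open ownership, see
#' [cell_index()]) and reads each layer there. Records falling outside
#' the grid or on a nodata cell in any variable are kept in the output
#' but flagged `valid = FALSE`; they must be excluded from modelling.
#'
#' @param stack An `eco_stack`.
#' @param occ A data frame with `longitude` and `latitude` columns
#'   (e.g. an occurrence table from [read_occurrences()]).
#' @return A tibble: the input columns, then `row`, `col`, one column
#'   per stack variable, and logicals `in_bounds`, `has_nodata`,
#'   `valid`.
#' @export
extract_at_points <- function(stack, occ) {
  stopifnot(all(c("longitude", "latitude") %in% names(occ)))
  ref <- stack$layers[[1L]]
  idx <- cell_index(ref, occ$longitude, occ$latitude)
  out <- dplyr::bind_cols(tibble::as_tibble(occ), idx)
  flat <- ifelse(is.na(idx$row), NA_integer_,
                 (idx$col - 1L) * nrow(ref$values) + idx$row)
  for (nm in names(stack$layers)) {
    v <- rep(NA_real_, nrow(out))
    ok <- !is.na(flat)
    v[ok] <- stack$layers[[nm]]$values[flat[ok]]
    out[[nm]] <- v
  }
  out$in_bounds <- !is.na(idx$row)
  vals <- as.matrix(out[names(stack$layers)])
  out$has_nodata <- out$in_bounds & apply(vals, 1L, anyNA)
  out$valid <- out$in_bounds & !out$has_nodata
  n_bad <- sum(!out$valid)
  if (n_bad > 0L)
    message(sprintf("extract_at_points: %d of %d records flagged (out of bounds or nodata)",
                    n_bad, nrow(out)))
  out
}

#' Variable columns of an extracted climate table
#'
#' @param climates A tibble from [extract_at_points()].
#' @param variables Variable names; defaults to every column that is
#'   neither a coordinate/bookkeeping column nor the species label.
#' @return Character vector of variable column names.
#' @export
climate_variables <- function(climates,
                              variables = NULL) {
  if (!is.null(variables)) return(variables)
  drop <- c("species", "longitude", "latitude", "source", "row", "col",
            "in_bounds", "has_nodata", "valid", "soil")
  setdiff(names(climates), drop)
}
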