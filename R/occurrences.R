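#' Read an occurrence table
#'
#' Reads delimited text with at least `species`, `longitude` and
#' `latitude` columns (an optional `source` column is carried through).
#' Coordinates are validated against [-180, 180] x [-90, 90]; offending
#' records are dropped with their row numbers reported to stderr.
#' Sampling bias is reduced the way herbarium workflows do it: when
#' `dedup` is on, exact duplicate (species, longitude, latitude) triples
#' are collapsed to the first record.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed from the header).
#' @param dedup Collapse exact duplicate triples (default `TRUE`).
#' @param cell_thin Optionally thin to one record per raster cell per
#'   species; off by default (exact-coordinate dedup is the standard
#'   behaviour). Requires `grid`.
#' @param grid An `eco_raster` defining cells for `cell_thin`.
#' @return A tibble with columns `species`, `longitude`, `latitude`
#'   and, if present, `source`.
#' @export
read_occurrences <- function(path, dedup = TRUE, cell_thin = FALSE,
                             grid = NULL) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  occurrence_table(df, dedup = dedup, cell_thin = cell_thin, grid = grid)
}

#' Validate a data frame of occurrence records
#'
#' The in-memory counterpart of [read_occurrences()]: same validation,
#' deduplication and logging, starting from a data frame.
#'
#' @inheritParams read_occurrences
#' @param df Data frame with `species`, `longitude`, `latitude` columns.
#' @return A tibble of validated records.
#' @export
occurrence_table <- function(df, dedup = TRUE, cell_thin = FALSE,
                             grid = NULL) {
  need <- c("species", "longitude", "latitude")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  keep <- intersect(c(need, "source"), names(df))
  out <- tibble::as_tibble(df[keep])
  out$longitude <- as.numeric(out$longitude)
  out$latitude <- as.numeric(out$latitude)
  bad <- is.na(out$longitude) | is.na(out$latitude) |
    out$longitude < -180 | out$longitude > 180 |
    out$latitude < -90 | out$latitude > 90
  if (any(bad)) {
    for (i in which(bad))
      message(sprintf("occurrences: row %d rejected (coordinate out of range: %s, %s)",
                      i, format(out$longitude[i]), format(out$latitude[i])))
    out <- out[!bad, ]
  }
  if (dedup) {
    n0 <- nrow(out)
    out <- dplyr::distinct(out, .data$species, .data$longitude,
                           .data$latitude, .keep_all = TRUE)
    if (nrow(out) < n0)
      message(sprintf("occurrences: %d exact duplicate record(s) removed", n0 - nrow(out)))
  }
  if (cell_thin) {
    if (is.null(grid)) stop("cell_thin requires a grid")
    idx <- cell_index(grid, out$longitude, out$latitude)
    out <- out[!duplicated(cbind(out$species, idx$row, idx$col)), ]
  }
  counts <- dplyr::count(out, .data$species)
  message(paste(sprintf("occurrences: %s n=%d", counts$species, counts$n),
                collapse = "; "))
  out
}

#' Write an occurrence table as CSV
#'
#' @param occ Occurrence tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
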