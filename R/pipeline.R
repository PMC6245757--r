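#' Run the full suitability pipeline
#'
#' Wires the stages together for one or more species: extract
#' occurrence climates, fit the envelope profile (range table + soil
#' set + clusters), predict the distance/suitability/mask surfaces,
#' account suitable area per region, and run the jackknife
#' variable-contribution analysis. Every artifact is written under
#' `out_dir` and listed (with MD5 checksums) in `manifest.csv`, so a
#' rerun with the same inputs and seed is byte-identical.
#'
#' Inputs may be in-memory objects or file paths (occurrence CSV,
#' ASCII-grid rasters, GeoJSON regions); a scene from
#' [generate_scene()] can be passed directly.
#'
#' @param occurrences Occurrence tibble or CSV path.
#' @param stack An `eco_stack` or named vector of ASCII-grid paths.
#' @param soil An `eco_raster`, an ASCII-grid path, or `NULL` to skip
#'   the soil intersection (`use_soil = FALSE`).
#' @param regions An `eco_regions` object or GeoJSON path, or `NULL`
#'   to skip area accounting.
#' @param out_dir Output directory (created if needed).
#' @param k,restarts,train_frac,seed Model options, recorded in the
#'   manifest.
#' @param use_soil Whether the soil intersection step is enabled.
#' @return A list per species of profile / surface / areas /
#'   contributions, plus the manifest tibble; invisibly.
#' @export
run_pipeline <- function(occurrences, stack, soil = NULL, regions = NULL,
                         out_dir = tempfile("ecosuit_run_"),
                         k = 1L, restarts = 10L, train_frac = 0.75,
                         seed = 1L, use_soil = TRUE) {
  stage <- function(name, species, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed for %s: %s",
                   name, species, conditionMessage(e)), call. = FALSE))
  }
  if (is.character(occurrences))
    occurrences <- read_occurrences(occurrences)
  if (is.character(stack)) stack <- read_stack(stack)
  if (is.character(soil)) soil <- read_ascii_grid(soil)
  if (is.character(regions)) regions <- read_geojson_regions(regions)
  if (use_soil && is.null(soil))
    stop("pipeline stage 'inputs' failed: soil step enabled but no soil raster given")
  if (!is.null(soil)) align_check(stack, soil, "soil")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  norm <- fit_normalization(stack)
  species_list <- unique(occurrences$species)
  results <- list()
  paths <- character(0L)
  all_areas <- list()
  safe <- function(s) gsub("[^A-Za-z0-9]+", "_", s)
  for (sp in species_list) {
    occ_sp <- occurrences[occurrences$species == sp, ]
    climates <- stage("extract", sp, extract_at_points(stack, occ_sp))
    if (use_soil) {
      idx <- cell_index(soil, occ_sp$longitude, occ_sp$latitude)
      flat <- (idx$col - 1L) * nrow(soil$values) + idx$row
      climates$soil <- soil$values[flat]
    }
    profile <- stage("profile", sp,
                     build_profile(climates, norm, species = sp, k = k,
                                   seed = seed, restarts = restarts))
    surface <- stage("predict", sp,
                     predict_suitability(stack, profile,
                                         soil = if (use_soil) soil else NULL))
    contrib <- stage("jackknife", sp,
                     jackknife_importance(stack, climates,
                                          train_frac = train_frac, k = k,
                                          seed = seed, restarts = restarts))
    base <- file.path(out_dir, safe(sp))
    utils::write.csv(tidy(profile), paste0(base, "_profile.csv"),
                     row.names = FALSE, quote = FALSE)
    write_ascii_grid(surface$suitability, paste0(base, "_suitability.asc"))
    write_ascii_grid(surface$mask, paste0(base, "_mask.asc"))
    utils::write.csv(as.data.frame(contrib), paste0(base, "_contributions.csv"),
                     row.names = FALSE, quote = FALSE)
    paths <- c(paths, paste0(base, c("_profile.csv", "_suitability.asc",
                                     "_mask.asc", "_contributions.csv")))
    areas <- NULL
    if (!is.null(regions)) {
      areas <- stage("areas", sp,
                     area_by_region(surface$mask, regions, species = sp))
      all_areas[[sp]] <- areas
    }
    results[[sp]] <- list(profile = profile, surface = surface,
                          contributions = contrib, areas = areas)
  }
  if (length(all_areas) > 0L) {
    combined <- dplyr::bind_rows(all_areas)
    area_path <- file.path(out_dir, "areas.csv")
    write_area_table(combined, area_path)
    paths <- c(paths, area_path)
    results$areas <- combined
  }
  manifest <- tibble::tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    seed = seed, k = k, train_frac = train_frac)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  results$manifest <- manifest
  results$out_dir <- out_dir
  invisible(results)
}
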