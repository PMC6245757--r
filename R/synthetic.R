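#' Default ecological variables of a virtual scene
#'
#' Six factors mirroring the standard medicinal-plant modelling set:
#' annual mean temperature (`T_aver`, deg C), warmest-quarter mean
#' (`T_warm`, deg C), coldest-quarter mean (`T_cold`, deg C), annual
#' precipitation (`Precipitation`, mm), annual radiation (`Radiation`,
#' W m-2) and annual relative humidity (`Humidity`, %). Each variable
#' is a linear spatial gradient (direction `angle_deg`, range
#' `vmin`-`vmax`) plus independent Gaussian cell noise `noise_sd`.
#' Temperature variables run west-east and moisture/radiation
#' variables south-north, so any envelope of value intervals has a
#' rectangular, analytically locatable spatial footprint.
#'
#' @return A tibble with columns `variable`, `vmin`, `vmax`,
#'   `angle_deg`, `noise_sd`.
#' @export
default_scene_variables <- function() {
  tibble::tibble(
    variable = c("T_aver", "T_warm", "T_cold", "Precipitation",
                 "Radiation", "Humidity"),
    vmin = c(-10, 0, -25, 0, 100, 30),
    vmax = c(30, 35, 25, 3000, 170, 85),
    angle_deg = c(0, 0, 0, 90, 90, 90),
    noise_sd = 0
  )
}

#' True ecological envelope of a virtual species
#'
#' The ground-truth analogue of a published per-species range table:
#' one closed [lo, hi] interval per variable plus the set of allowed
#' soil classes. The default intervals mirror a published envelope of
#' a temperate *Dioscorea* yam (annual mean temperature 7.4-24.2 deg C,
#' warmest quarter 16.6-28.7, coldest quarter -3.5-18.8, precipitation
#' 543-1849 mm, radiation 117.7-150.4 W m-2, humidity 52.9-76.0 %).
#'
#' @param ranges Tibble with `variable`, `lo`, `hi` (lo <= hi), or a
#'   list of such tibbles for a multi-component (disjoint) niche.
#' @param soil_classes Non-empty integer vector of allowed soil ids.
#' @return An object of class `eco_truth`.
#' @export
true_envelope <- function(ranges = NULL, soil_classes = 1:4) {
  if (is.null(ranges)) {
    ranges <- tibble::tibble(
      variable = c("T_aver", "T_warm", "T_cold", "Precipitation",
                   "Radiation", "Humidity"),
      lo = c(7.4, 16.6, -3.5, 543, 117.7, 52.9),
      hi = c(24.2, 28.7, 18.8, 1849, 150.39, 76.0))
  }
  if (is.data.frame(ranges)) ranges <- list(ranges)
  for (comp in ranges) {
    stopifnot(all(c("variable", "lo", "hi") %in% names(comp)))
    if (any(comp$lo > comp$hi)) stop("interval lo must be <= hi")
  }
  if (length(soil_classes) == 0L) stop("soil-class set must be non-empty")
  structure(list(components = ranges, soil_classes = sort(unique(soil_classes))),
            class = "eco_truth")
}

#' @export
print.eco_truth <- function(x, ...) {
  cat(sprintf("<eco_truth> %d component(s), soil classes {%s}\n",
              length(x$components),
              paste(x$soil_classes, collapse = ", ")))
  print(x$components[[1L]])
  invisible(x)
}

#' Configuration of a virtual-species scene
#'
#' @param nrow,ncol Grid dimensions (>= 2 each).
#' @param bounds Geographic bounds `c(west, east, south, north)` in
#'   degrees, within [-180, 180] x [-90, 90]. The default 20 x 20
#'   degree window yields square 0.5-degree cells on a 40 x 40 grid.
#' @param variables Variable table as in [default_scene_variables()].
#' @param n_soil Number of soil classes in the Voronoi mosaic.
#' @param n_occ Number of occurrence records to draw (>= 1).
#' @param detection_noise Fraction of occurrences re-sampled uniformly
#'   over the whole grid (a simple mis-georeferencing model); 0 = all
#'   records fall inside the true niche.
#' @param species Species label for the generated records.
#' @param seed Integer seed; every random draw in the scene flows from
#'   it.
#' @return An object of class `eco_scene_config`.
#' @export
scene_config <- function(nrow = 40L, ncol = 40L,
                         bounds = c(-10, 10, -10, 10),
                         variables = default_scene_variables(),
                         n_soil = 8L, n_occ = 200L,
                         detection_noise = 0, species = "Virtual yam",
                         seed = 1L) {
  if (nrow < 2L || ncol < 2L) stop("grid must be at least 2 x 2")
  if (n_occ < 1L) stop("n_occ must be >= 1")
  if (any(variables$noise_sd < 0)) stop("noise sd must be >= 0")
  if (bounds[1L] < -180 || bounds[2L] > 180 ||
      bounds[3L] < -90 || bounds[4L] > 90 ||
      bounds[1L] >= bounds[2L] || bounds[3L] >= bounds[4L])
    stop("bounds must be c(west, east, south, north) within the globe")
  if (detection_noise < 0 || detection_noise > 1)
    stop("detection_noise must be in [0, 1]")
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 bounds = bounds, variables = variables,
                 n_soil = as.integer(n_soil), n_occ = as.integer(n_occ),
                 detection_noise = detection_noise, species = species,
                 seed = as.integer(seed)),
            class = "eco_scene_config")
}

inside_truth <- function(vals, truth) {
  ## vals: matrix cells x variables (native units, named columns)
  inside_any <- rep(FALSE, nrow(vals))
  for (comp in truth$components) {
    ok <- rep(TRUE, nrow(vals))
    for (i in seq_len(nrow(comp))) {
      v <- vals[, comp$variable[i]]
      ok <- ok & v >= comp$lo[i] & v <= comp$hi[i]
    }
    inside_any <- inside_any | ok
  }
  inside_any
}

#' Generate a virtual-species scene
#'
#' Builds co-registered climate layers (linear gradients plus Gaussian
#' noise), a Voronoi soil-class mosaic, a 2 x 2 block of rectangular
#' administrative regions grouped into two continents, and `n_occ`
#' occurrence records placed at centers of cells whose climate vector
#' lies inside the true envelope and whose soil class is allowed.
#' With `detection_noise > 0`, that fraction of records is re-sampled
#' uniformly over the grid. Generation is a pure function of
#' `config$seed`.
#'
#' @param config An [scene_config()] object.
#' @param truth A [true_envelope()] object; its intervals must admit at
#'   least one cell, else an "empty niche" error names the most
#'   restrictive variable.
#' @return A list: `stack` (`eco_stack`), `soil` (`eco_raster`),
#'   `regions` (`eco_regions`), `occurrences` (tibble),
#'   `truth_mask` (`eco_raster`, the true suitable footprint), and the
#'   `config` / `truth` inputs.
#' @export
generate_scene <- function(config = scene_config(),
                           truth = true_envelope()) {
  set.seed(config$seed)
  nr <- config$nrow; nc <- config$ncol
  west <- config$bounds[1L]; east <- config$bounds[2L]
  south <- config$bounds[3L]; north <- config$bounds[4L]
  dx <- (east - west) / nc
  dy <- (north - south) / nr
  ## unit cell-center coordinates in [0, 1] for the gradient field
  cx <- (rep(seq_len(nc), each = nr) - 0.5) / nc
  cy <- (nr - rep(seq_len(nr), times = nc) + 0.5) / nr   # 0 at south
  vars <- config$variables
  layers <- list()
  vals <- matrix(NA_real_, nrow = nr * nc, ncol = nrow(vars),
                 dimnames = list(NULL, vars$variable))
  for (i in seq_len(nrow(vars))) {
    th <- vars$angle_deg[i] * pi / 180
    t_raw <- cx * cos(th) + cy * sin(th)
    t01 <- (t_raw - min(t_raw)) / (max(t_raw) - min(t_raw))
    v <- vars$vmin[i] + t01 * (vars$vmax[i] - vars$vmin[i])
    if (vars$noise_sd[i] > 0)
      v <- v + stats::rnorm(length(v), 0, vars$noise_sd[i])
    vals[, i] <- v
    layers[[vars$variable[i]]] <- eco_raster(
      matrix(v, nrow = nr), west = west, north = north,
      dx = dx, dy = dy)
  }
  stack <- variable_stack(layers)
  ## Voronoi soil mosaic: each class owns several seeded patches, the
  ## way soil classes recur across a landscape
  n_ctr <- config$n_soil * 3L
  ctr_col <- stats::runif(n_ctr, 0, nc)
  ctr_row <- stats::runif(n_ctr, 0, nr)
  ctr_class <- rep(seq_len(config$n_soil), length.out = n_ctr)
  cell_col <- rep(seq_len(nc), each = nr) - 0.5
  cell_row <- rep(seq_len(nr), times = nc) - 0.5
  d2 <- outer(cell_col, ctr_col, `-`)^2 + outer(cell_row, ctr_row, `-`)^2
  soil_class <- ctr_class[max.col(-d2, ties.method = "first")]
  soil <- eco_raster(matrix(as.numeric(soil_class), nrow = nr),
                     west = west, north = north, dx = dx, dy = dy)
  ## true niche footprint
  climate_ok <- inside_truth(vals, truth)
  ok <- climate_ok & soil_class %in% truth$soil_classes
  if (!any(ok) && any(climate_ok))
    stop("empty niche: no cell satisfies the true envelope; most restrictive variable: soil")
  if (!any(ok)) {
    counts <- vapply(seq_len(nrow(vars)), function(i) {
      comp_ok <- vapply(truth$components, function(comp) {
        j <- match(vars$variable[i], comp$variable)
        if (is.na(j)) rep(TRUE, nrow(vals))
        else vals[, i] >= comp$lo[j] & vals[, i] <= comp$hi[j]
      }, logical(nrow(vals)))
      sum(rowSums(comp_ok) > 0)
    }, numeric(1L))
    stop(sprintf("empty niche: no cell satisfies the true envelope; most restrictive variable: %s",
                 vars$variable[which.min(counts)]))
  }
  truth_mask <- eco_raster(matrix(ok + 0, nrow = nr), west = west,
                           north = north, dx = dx, dy = dy)
  ## occurrences at centers of suitable cells (index into the pool so a
  ## single-cell niche does not trigger sample()'s scalar expansion)
  pool <- which(ok)
  flat <- pool[sample.int(length(pool), config$n_occ, replace = TRUE)]
  n_noise <- round(config$detection_noise * config$n_occ)
  if (n_noise > 0L) {
    idx <- sample.int(config$n_occ, n_noise)
    flat[idx] <- sample.int(nr * nc, n_noise, replace = TRUE)
  }
  row <- (flat - 1L) %% nr + 1L
  col <- (flat - 1L) %/% nr + 1L
  ctr <- cell_center(stack$layers[[1L]], row, col)
  occurrences <- tibble::tibble(species = config$species,
                                longitude = ctr$lon, latitude = ctr$lat,
                                source = "synthetic")
  regions <- grid_regions(west, east, south, north)
  list(stack = stack, soil = soil, regions = regions,
       occurrences = occurrences, truth_mask = truth_mask,
       config = config, truth = truth)
}

#' Rectangular region hierarchy over a bounding box
#'
#' Splits the box into a 2 x 2 block of rectangular "countries"
#' grouped into two "continents" (west and east halves) — a minimal
#' stand-in for an administrative-boundary database, adequate for
#' exercising point-in-polygon area accounting.
#'
#' @param west,east,south,north Bounding box in degrees.
#' @return An `eco_regions` object.
#' @export
grid_regions <- function(west, east, south, north) {
  mx <- (west + east) / 2
  my <- (south + north) / 2
  rect <- function(w, e, s, n)
    matrix(c(w, s, e, s, e, n, w, n, w, s), ncol = 2L, byrow = TRUE)
  region_set(
    name = c("Westland North", "Westland South",
             "Eastland North", "Eastland South",
             "Westland", "Eastland"),
    level = c(rep("country", 4L), rep("continent", 2L)),
    parent = c("Westland", "Westland", "Eastland", "Eastland", NA, NA),
    geometry = list(
      rect(west, mx, my, north), rect(west, mx, south, my),
      rect(mx, east, my, north), rect(mx, east, south, my),
      rect(west, mx, south, north), rect(mx, east, south, north))
  )
}

## K80 transition probabilities for one branch of expected length d
## (substitutions/site) and instantaneous transition/transversion rate
## ratio kappa. Returns c(same, transition, each transversion).
k80_edge_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv = 0.25 - 0.25 * e1)
}

#' Simulate an alignment under the two-parameter substitution model
#'
#' Evolves nucleotide sequences along a tree under the Kimura
#' two-parameter process, with branch lengths in expected
#' substitutions per site — so the expected K2P distance between two
#' leaves equals their path length. Transition probabilities per edge
#' use the exact closed form.
#'
#' @param tree An ape `phylo` tree with non-negative branch lengths
#'   (negative lengths are an error; zero-length branches transmit the
#'   sequence unchanged).
#' @param length Number of sites (>= 1).
#' @param rate_ratio Instantaneous transition/transversion rate ratio
#'   kappa (default 2).
#' @param seed Integer seed.
#' @return An `eco_alignment` with one row per leaf.
#' @export
simulate_alignment <- function(tree, length, rate_ratio = 2, seed = 1L) {
  if (length < 1L) stop("length must be >= 1")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  set.seed(seed)
  n <- base::length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  seqs <- vector("list", n_nodes)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  seqs[[root]] <- sample.int(4L, length, replace = TRUE)
  ## breadth-first from the root: parents always simulated first
  kids_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  queue <- root
  ord <- integer(0L)
  while (base::length(queue) > 0L) {
    node <- queue[1L]; queue <- queue[-1L]
    edges_here <- kids_of[[as.character(node)]]
    ord <- c(ord, edges_here)
    queue <- c(queue, tree$edge[edges_here, 2L])
  }
  for (e in ord) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    p <- k80_edge_probs(tree$edge.length[e], rate_ratio)
    par_seq <- seqs[[parent]]
    child_seq <- integer(length)
    for (b in 1:4) {
      at <- which(par_seq == b)
      if (base::length(at) == 0L) next
      tvs <- setdiff(1:4, c(b, TS_PARTNER[b]))
      outcomes <- c(b, TS_PARTNER[b], tvs)
      child_seq[at] <- outcomes[sample.int(4L, base::length(at),
                                           replace = TRUE,
                                           prob = c(p["same"], p["ts"],
                                                    p["tv"], p["tv"]))]
    }
    seqs[[child]] <- child_seq
  }
  m <- do.call(rbind, lapply(seq_len(n), function(i) BASES[seqs[[i]]]))
  rownames(m) <- tree$tip.label
  sequence_alignment(m)
}
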