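# Shared fixtures and independent oracles, all built in code.

make_stack <- function(mats, west = 0, north = 10, dx = 1, dy = 1) {
  variable_stack(lapply(mats, function(m)
    eco_raster(m, west = west, north = north, dx = dx, dy = dy)))
}

# Attach the soil class under each occurrence record.
attach_soil <- function(climates, soil) {
  idx <- cell_index(soil, climates$longitude, climates$latitude)
  flat <- (idx$col - 1L) * nrow(soil$values) + idx$row
  climates$soil <- soil$values[flat]
  climates
}

occurrence_climates <- function(scene) {
  cl <- suppressMessages(extract_at_points(scene$stack, scene$occurrences))
  attach_soil(cl, scene$soil)
}

# Scalar oracle for the per-variable range distance: plain if/else,
# independent of the package's vectorized implementation.
oracle_component <- function(v, lo, hi) {
  if (v >= lo && v <= hi) 0 else min(abs(v - lo), abs(v - hi))
}

oracle_point_distance <- function(p, lo, hi) {
  sqrt(sum(vapply(seq_along(p), function(i)
    oracle_component(p[i], lo[i], hi[i]), numeric(1))^2))
}

# Brute-force objective of a partition: scopes as member min/max
# boxes, E as the sum of squared distances, all in plain loops.
oracle_E <- function(P, assignment) {
  total <- 0
  for (j in unique(assignment)) {
    m <- P[assignment == j, , drop = FALSE]
    lo <- apply(m, 2, min); hi <- apply(m, 2, max)
    for (r in seq_len(nrow(m)))
      total <- total + oracle_point_distance(m[r, ], lo, hi)^2
  }
  total
}

oracle_extent <- function(P, assignment) {
  total <- 0
  for (j in unique(assignment)) {
    m <- P[assignment == j, , drop = FALSE]
    total <- total + sum((apply(m, 2, max) - apply(m, 2, min))^2)
  }
  total
}

# Exhaustive search over all 2-partitions (both clusters non-empty);
# returns the lexicographic (E, extent) minimum and its partition.
oracle_best_2partition <- function(P) {
  n <- nrow(P)
  best <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    assignment <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(assignment)) < 2L) next
    E <- oracle_E(P, assignment)
    ext <- oracle_extent(P, assignment)
    if (is.null(best) || E < best$E - 1e-12 ||
        (abs(E - best$E) <= 1e-12 && ext < best$extent - 1e-12)) {
      best <- list(E = E, extent = ext, assignment = assignment)
    }
  }
  best
}

# Scene where exactly one variable (Precipitation) constrains the
# niche; the gradient directions are all distinct so no variable
# duplicates another.
one_constraint_scene <- function(seed, n_occ = 120) {
  vars <- default_scene_variables()
  vars$angle_deg <- c(0, 30, 60, 90, 120, 150)
  tr <- tibble::tibble(variable = vars$variable, lo = vars$vmin,
                       hi = vars$vmax)
  tr$lo[tr$variable == "Precipitation"] <- 800
  tr$hi[tr$variable == "Precipitation"] <- 1400
  generate_scene(
    scene_config(variables = vars, n_occ = n_occ, seed = seed),
    true_envelope(tr, soil_classes = 1:8))
}

# K2P sampling variance (delta method) for the standard-error oracle.
oracle_k2p_se <- function(P, Q, n) {
  c1 <- 1 / (1 - 2 * P - Q)
  c2 <- 1 / (1 - 2 * Q)
  c3 <- (c1 + c2) / 2
  sqrt((c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n)
}

# Convert the package alignment to ape's DNAbin for oracle distances.
as_dnabin <- function(aln) {
  ape::as.DNAbin(lapply(stats::setNames(rownames(aln), rownames(aln)),
                        function(nm) tolower(unclass(aln)[nm, ])))
}
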