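#' Fit per-layer normalization statistics
#'
#' Linear rescaling of every climate layer to a common 0-100 scale:
#' v' = (v - min_A) / (max_A - min_A) * 100, with min_A / max_A the
#' layer minimum and maximum over valid (non-nodata) cells. The
#' statistics come from the layers, not from the occurrences, so
#' occurrence values outside the layer range extrapolate linearly
#' beyond [0, 100] rather than being clipped.
#'
#' @param stack An `eco_stack` of climate layers.
#' @return An object of class `eco_norm`: a tibble with `variable`,
#'   `min`, `max` and the fixed target range [0, 100].
#' @export
fit_normalization <- function(stack) {
  out <- purrr::map_dfr(names(stack$layers), function(nm) {
    v <- stack$layers[[nm]]$values
    lo <- min(v, na.rm = TRUE)
    hi <- max(v, na.rm = TRUE)
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
      stop(sprintf("layer '%s' is constant or empty; cannot normalize", nm))
    tibble::tibble(variable = nm, min = lo, max = hi)
  })
  structure(out, class = c("eco_norm", class(out)),
            new_min = 0, new_max = 100)
}

#' Normalize native-unit values
#'
#' @param v Numeric vector of native-unit values.
#' @param norm An `eco_norm` object.
#' @param variable Which variable's statistics to use.
#' @return Normalized values on the 0-100 scale (linear, not clipped).
#' @export
normalize_value <- function(v, norm, variable) {
  i <- match(variable, norm$variable)
  if (is.na(i)) stop(sprintf("unknown variable '%s'", variable))
  (v - norm$min[i]) / (norm$max[i] - norm$min[i]) * 100
}

#' Normalize a climate table or matrix column-wise
#'
#' @param x Data frame or matrix whose columns include the variables
#'   in `norm` (extra columns are dropped).
#' @param norm An `eco_norm` object.
#' @return A numeric matrix, one column per variable in `norm`'s order.
#' @export
normalize_values <- function(x, norm) {
  x <- as.data.frame(x)
  miss <- setdiff(norm$variable, names(x))
  if (length(miss) > 0L)
    stop(sprintf("missing variable column(s): %s", paste(miss, collapse = ", ")))
  m <- vapply(seq_len(nrow(norm)), function(i)
    normalize_value(x[[norm$variable[i]]], norm, norm$variable[i]),
    numeric(nrow(x)))
  m <- matrix(m, nrow = nrow(x), ncol = nrow(norm))
  colnames(m) <- norm$variable
  m
}

#' Back-transform normalized values to native units
#'
#' @inheritParams normalize_value
#' @export
denormalize_value <- function(v, norm, variable) {
  i <- match(variable, norm$variable)
  if (is.na(i)) stop(sprintf("unknown variable '%s'", variable))
  v / 100 * (norm$max[i] - norm$min[i]) + norm$min[i]
}

## Per-variable range distance of each row of P to the box [lo, hi]:
## 0 inside, else distance to the nearer bound.
range_component <- function(P, lo, hi) {
  pmax(sweep(-P, 2L, lo, `+`), sweep(P, 2L, hi, `-`), 0)
}

#' Range distance of a point to a cluster scope
#'
#' A cluster's scope is its per-variable [min, max] hyper-rectangle.
#' The per-variable distance is 0 when the value lies inside the range
#' and the distance to the nearer bound otherwise; variables aggregate
#' as the Euclidean norm. Its square is the summand of the clustering
#' objective E.
#'
#' @param p Numeric vector (one point, normalized units) or a matrix of
#'   points in rows.
#' @param scope A two-row matrix or a data frame with `min` and `max`
#'   (columns/rows ordered as `p`'s variables).
#' @return Numeric vector of distances, one per point.
#' @export
point_distance <- function(p, scope) {
  if (is.data.frame(scope)) scope <- rbind(scope$min, scope$max)
  if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
  if (ncol(p) != ncol(scope))
    stop(sprintf("dimension mismatch: point has %d variables, scope %d",
                 ncol(p), ncol(scope)))
  cv <- range_component(p, scope[1L, ], scope[2L, ])
  sqrt(rowSums(cv^2))
}

scopes_from_assignment <- function(P, assignment, k) {
  lapply(seq_len(k), function(j) {
    m <- P[assignment == j, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    rbind(apply(m, 2L, min), apply(m, 2L, max))
  })
}

#' Clustering objective E of a partition
#'
#' Brute-force evaluation of the range-based k-means objective: with
#' each cluster's scope recomputed as the per-variable [min, max] over
#' its members, E is the sum over points of the squared range distance
#' to their own cluster's scope. Every member lies inside its own
#' cluster's bounding box, so E is 0 for any converged partition; the
#' function exists to assert that consistency and to score candidate
#' partitions mid-iteration.
#'
#' @param P Matrix of normalized climate points (rows).
#' @param assignment Integer cluster label per row.
#' @param scopes Optional list of 2-row scope matrices to evaluate
#'   against; by default recomputed from the partition.
#' @return The objective value E (>= 0).
#' @export
eq_b_objective <- function(P, assignment, scopes = NULL) {
  k <- max(assignment)
  if (is.null(scopes)) scopes <- scopes_from_assignment(P, assignment, k)
  total <- 0
  for (j in seq_len(k)) {
    m <- P[assignment == j, , drop = FALSE]
    if (nrow(m) == 0L || is.null(scopes[[j]])) next
    total <- total + sum(point_distance(m, scopes[[j]])^2)
  }
  total
}

## Secondary selection criterion: total squared scope width. E alone
## cannot rank converged partitions (it is identically 0 once scopes
## are recomputed from members), so among equal-E solutions the fit
## keeps the partition with the tightest boxes.
scope_extent <- function(scopes) {
  sum(vapply(scopes, function(s) {
    if (is.null(s)) 0 else sum((s[2L, ] - s[1L, ])^2)
  }, numeric(1L)))
}

fit_clusters_once <- function(P, k, seed, max_iter, tol) {
  n <- nrow(P)
  set.seed(seed)
  centers <- sample.int(n, k)
  scopes <- lapply(centers, function(i) rbind(P[i, ], P[i, ]))
  assignment <- rep(0L, n)
  E_trace <- numeric(0L)
  for (iter in seq_len(max_iter)) {
    D <- vapply(scopes, function(s) point_distance(P, s), numeric(n))
    D <- matrix(D, nrow = n, ncol = k)
    new_assign <- max.col(-D, ties.method = "first")
    d_min <- D[cbind(seq_len(n), new_assign)]
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {
        far <- which.max(d_min)
        new_assign[far] <- j
        d_min[far] <- 0
      }
    }
    E_iter <- sum(d_min^2)
    E_trace <- c(E_trace, E_iter)
    converged <- identical(new_assign, assignment) ||
      (iter > 1L && E_trace[iter - 1L] - E_iter < tol &&
         identical(new_assign, assignment))
    assignment <- new_assign
    scopes <- scopes_from_assignment(P, assignment, k)
    if (converged) break
  }
  E <- eq_b_objective(P, assignment, scopes)
  list(assignment = assignment, scopes = scopes, E = E,
       E_trace = E_trace, extent = scope_extent(scopes),
       iterations = length(E_trace))
}

#' Range-based k-means clustering of occurrence climates
#'
#' Occurrence climate points (normalized units) are grouped by an
#' improved k-means that replaces centroids with range scopes: each
#' cluster is its members' per-variable [min, max] box, points are
#' assigned to the cluster with the smallest range distance (ties to
#' the lowest cluster index), and the objective E sums squared range
#' distances over points. Assignment and scope update alternate until
#' the assignment is stable; a cluster that empties is re-seeded from
#' the point farthest from its assigned scope. The best of `restarts`
#' random restarts (seeds `seed + 0 ... seed + restarts - 1`) is kept,
#' ranked lexicographically by (E, total squared scope width) — the
#' width tie-break is needed because E is 0 at every converged
#' partition.
#'
#' @param points Matrix or data frame of normalized climate values,
#'   one row per occurrence.
#' @param k Number of clusters (1 <= k <= n). The default 1 reproduces
#'   a single per-species range table.
#' @param seed Integer seed; all randomness derives from it.
#' @param restarts Number of random restarts (default 10).
#' @param max_iter Iteration cap per restart.
#' @param tol Convergence tolerance on E improvement.
#' @return An object of class `eco_clusters`.
#' @export
fit_clusters <- function(points, k = 1L, seed = 1L, restarts = 10L,
                         max_iter = 100L, tol = 1e-9) {
  P <- as.matrix(points)
  storage.mode(P) <- "double"
  n <- nrow(P)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop(sprintf("k = %d exceeds the number of points (%d)", k, n))
  if (anyNA(P)) stop("points must not contain missing values")
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- fit_clusters_once(P, k, seed + r - 1L, max_iter, tol)
    if (is.null(best) ||
        fit$E < best$E - 1e-12 ||
        (abs(fit$E - best$E) <= 1e-12 && fit$extent < best$extent - 1e-12)) {
      best <- fit
      best$restart <- r
    }
  }
  structure(
    list(k = as.integer(k), assignment = best$assignment,
         scopes = best$scopes, E = best$E, E_trace = best$E_trace,
         extent = best$extent, iterations = best$iterations,
         restart = best$restart, variables = colnames(P), seed = seed),
    class = "eco_clusters"
  )
}

#' @export
print.eco_clusters <- function(x, ...) {
  cat(sprintf("<eco_clusters> k = %d, n = %d, E = %g (restart %d, %d iterations)\n",
              x$k, length(x$assignment), x$E, x$restart, x$iterations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster fit into one row per cluster and variable
#'
#' @param x An `eco_clusters` object.
#' @param ... Unused.
#' @return A tibble with `cluster`, `variable`, `min`, `max`, `n`.
#' @export
tidy.eco_clusters <- function(x, ...) {
  vars <- x$variables %||% paste0("V", seq_len(ncol(x$scopes[[1L]])))
  purrr::map_dfr(seq_len(x$k), function(j) {
    s <- x$scopes[[j]]
    tibble::tibble(cluster = j, variable = vars,
                   min = s[1L, ], max = s[2L, ],
                   n = sum(x$assignment == j))
  })
}

#' @export
glance.eco_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$assignment), E = x$E,
                 extent = x$extent, iterations = x$iterations,
                 restart = x$restart)
}

#' Build a species envelope profile
#'
#' The per-species analogue of a published range table: per-variable
#' [min, max] in native units over the valid occurrence records, the
#' set of soil classes observed at occurrence cells, and the
#' range-cluster structure fitted on normalized values.
#'
#' @param climates Tibble of occurrence climate values (e.g. from
#'   [extract_at_points()]); rows with `valid == FALSE` are dropped if
#'   the column is present.
#' @param norm An `eco_norm` fitted on the climate stack.
#' @param species Species name for the profile.
#' @param soil Integer vector of soil classes at the occurrence cells,
#'   or `NULL` to take a `soil` column of `climates`; `NULL` soil means
#'   no soil constraint.
#' @param k,seed,restarts Clustering controls, see [fit_clusters()].
#' @return An object of class `eco_profile`.
#' @export
build_profile <- function(climates, norm, species = "species",
                          soil = NULL, k = 1L, seed = 1L, restarts = 10L) {
  if ("valid" %in% names(climates)) {
    if (is.null(soil) && "soil" %in% names(climates))
      soil <- climates$soil[climates$valid]
    climates <- climates[climates$valid, ]
  } else if (is.null(soil) && "soil" %in% names(climates)) {
    soil <- climates$soil
  }
  if (nrow(climates) == 0L) stop("no valid occurrence records")
  ranges <- purrr::map_dfr(norm$variable, function(nm) {
    v <- climates[[nm]]
    if (is.null(v)) stop(sprintf("missing variable column '%s'", nm))
    tibble::tibble(variable = nm, min = min(v), max = max(v))
  })
  soil_classes <- if (is.null(soil)) NULL else sort(unique(soil[!is.na(soil)]))
  P <- normalize_values(climates, norm)
  clusters <- fit_clusters(P, k = min(k, nrow(P)), seed = seed,
                           restarts = restarts)
  structure(
    list(species = species, ranges = ranges, soil_classes = soil_classes,
         clusters = clusters, norm = norm),
    class = "eco_profile"
  )
}

#' @export
print.eco_profile <- function(x, ...) {
  cat(sprintf("<eco_profile> %s: %d variables, k = %d cluster(s), %s\n",
              x$species, nrow(x$ranges), x$clusters$k,
              if (is.null(x$soil_classes)) "no soil constraint"
              else sprintf("%d soil class(es)", length(x$soil_classes))))
  print(x$ranges)
  invisible(x)
}

#' Tidy an envelope profile into its range table
#'
#' One row per variable: the native-unit [min, max] envelope (the
#' published-table format).
#'
#' @param x An `eco_profile`.
#' @param ... Unused.
#' @export
tidy.eco_profile <- function(x, ...) {
  dplyr::mutate(x$ranges, species = x$species, .before = 1L)
}

#' @export
glance.eco_profile <- function(x, ...) {
  tibble::tibble(species = x$species, n_occurrences = length(x$clusters$assignment),
                 n_variables = nrow(x$ranges), k = x$clusters$k,
                 E = x$clusters$E,
                 n_soil_classes = if (is.null(x$soil_classes)) NA_integer_
                 else length(x$soil_classes))
}

#' Envelope distance surface
#'
#' For every valid cell of the stack, the range distance (normalized
#' units) from the cell's climate vector to the nearest cluster scope
#' of the profile; 0 inside the envelope. Nodata propagates.
#'
#' @param stack An `eco_stack` with exactly the profile's variable set.
#' @param profile An `eco_profile`.
#' @return An object of class `eco_surface` holding the distance
#'   raster; complete it with [suitability_transform()].
#' @export
distance_surface <- function(stack, profile) {
  vars <- profile$norm$variable
  if (!setequal(names(stack$layers), vars))
    stop(sprintf("variable set mismatch: stack has [%s], profile has [%s]",
                 paste(names(stack$layers), collapse = ", "),
                 paste(vars, collapse = ", ")))
  ref <- stack$layers[[vars[1L]]]
  M <- vapply(vars, function(nm) as.vector(stack$layers[[nm]]$values),
              numeric(length(ref$values)))
  valid <- !apply(M, 1L, anyNA)
  Pn <- normalize_values(as.data.frame(M)[valid, , drop = FALSE],
                         profile$norm)
  D <- vapply(profile$clusters$scopes, function(s) point_distance(Pn, s),
              numeric(nrow(Pn)))
  D <- matrix(D, nrow = nrow(Pn))
  d_min <- apply(D, 1L, min)
  out <- rep(NA_real_, length(valid))
  out[valid] <- d_min
  dist_r <- eco_raster(matrix(out, nrow = nrow(ref$values)),
                       west = ref$west, north = ref$north,
                       dx = ref$dx, dy = ref$dy,
                       nodata = ref$nodata, crs = ref$crs)
  structure(
    list(species = profile$species, distance = dist_r,
         suitability = NULL, mask = NULL, sigma = NULL),
    class = "eco_surface"
  )
}

#' Complete a suitability surface
#'
#' Maps envelope distance D to a bounded suitability index
#' s = 0.999 * exp(-D / sigma), so s = 0.999 (best habitat) at D = 0
#' and s tends to 0 as D grows; sigma is the median of the positive
#' distances over valid cells (1 when every cell has D = 0). Cells
#' whose soil class is not in the profile's allowed set get s = 0. The
#' binary suitable mask — the layer all area accounting uses — is
#' threshold-free: D = 0 and soil allowed.
#'
#' @param surface An `eco_surface` from [distance_surface()].
#' @param soil Categorical soil `eco_raster` co-registered with the
#'   distance grid, or `NULL` for no soil constraint.
#' @param profile The `eco_profile` that produced `surface`.
#' @return The completed `eco_surface` (distance, suitability, mask).
#' @export
suitability_transform <- function(surface, soil = NULL, profile) {
  D <- surface$distance$values
  pos <- D[!is.na(D) & D > 0]
  sigma <- if (length(pos) > 0L) stats::median(pos) else 1
  s <- 0.999 * exp(-D / sigma)
  allowed <- matrix(TRUE, nrow = nrow(D), ncol = ncol(D))
  if (!is.null(soil) && !is.null(profile$soil_classes)) {
    check_aligned(surface$distance, soil, "soil")
    allowed <- matrix(soil$values %in% profile$soil_classes,
                      nrow = nrow(D))
    allowed[is.na(soil$values)] <- NA
  }
  s[allowed %in% FALSE] <- 0
  s[is.na(allowed)] <- NA
  mask <- (D == 0) & allowed
  r <- surface$distance
  surface$suitability <- eco_raster(s, r$west, r$north, r$dx, r$dy,
                                    r$nodata, r$crs)
  surface$mask <- eco_raster(mask + 0, r$west, r$north, r$dx, r$dy,
                             r$nodata, r$crs)
  surface$sigma <- sigma
  surface
}

#' One-call suitability prediction
#'
#' [distance_surface()] followed by [suitability_transform()].
#'
#' @inheritParams distance_surface
#' @inheritParams suitability_transform
#' @export
predict_suitability <- function(stack, profile, soil = NULL) {
  suitability_transform(distance_surface(stack, profile), soil, profile)
}

#' @export
print.eco_surface <- function(x, ...) {
  done <- !is.null(x$suitability)
  cat(sprintf("<eco_surface> %s: %s\n", x$species,
              if (done) sprintf("complete (sigma = %g, %d suitable cells)",
                                x$sigma, sum(x$mask$values == 1, na.rm = TRUE))
              else "distance only"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
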