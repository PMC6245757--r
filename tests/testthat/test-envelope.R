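toy_norm <- function() {
  stack <- make_stack(list(
    x = matrix(seq(0, 100, length.out = 16), 4),
    y = matrix(seq(-50, 50, length.out = 16), 4)))
  fit_normalization(stack)
}

test_that("normalization is the linear 0-100 map with extrapolation", {
  norm <- toy_norm()
  expect_equal(normalize_value(0, norm, "x"), 0)
  expect_equal(normalize_value(100, norm, "x"), 100)
  expect_equal(normalize_value(50, norm, "x"), 50)
  expect_equal(normalize_value(-50, norm, "y"), 0)
  expect_equal(normalize_value(0, norm, "y"), 50)
  # values beyond the layer range extrapolate, they are not clipped
  expect_equal(normalize_value(125, norm, "x"), 125)
  expect_equal(normalize_value(-10, norm, "x"), -10)
  expect_equal(denormalize_value(normalize_value(37.3, norm, "y"), norm, "y"),
               37.3)
  # constant layers are rejected at fit time
  expect_error(fit_normalization(make_stack(list(c = matrix(5, 3, 3)))),
               "constant")
})

test_that("range distance follows the inside-zero / nearest-bound rule", {
  # inside on all variables
  expect_equal(point_distance(c(50, 50), data.frame(min = c(30, 40),
                                                    max = c(70, 60))), 0)
  # 1-D below the range: distance to the lower bound
  expect_equal(point_distance(20, data.frame(min = 30, max = 70)), 10)
  # Euclidean aggregation across variables: (3, 4) -> 5
  expect_equal(point_distance(c(27, 74), data.frame(min = c(30, 40),
                                                    max = c(70, 70))), 5)
  expect_error(point_distance(c(1, 2, 3), data.frame(min = 1, max = 2)),
               "dimension mismatch")
})

test_that("per-variable distances match the scalar oracle on random cases", {
  set.seed(99)
  for (i in 1:250) {
    m <- sample(1:4, 1)
    lo <- runif(m, 0, 50)
    hi <- lo + runif(m, 0, 50)
    p <- runif(m, -20, 120)
    expect_equal(point_distance(p, rbind(lo, hi)),
                 oracle_point_distance(p, lo, hi))
  }
})

test_that("k = 1 and k = n give zero-objective degenerate fits", {
  set.seed(12)
  P <- matrix(runif(24, 0, 100), 8)
  one <- fit_clusters(P, k = 1, seed = 1)
  expect_equal(one$E, 0)
  expect_equal(one$scopes[[1]][1, ], apply(P, 2, min))
  expect_equal(one$scopes[[1]][2, ], apply(P, 2, max))
  all_k <- fit_clusters(P, k = 8, seed = 1)
  expect_equal(all_k$E, 0)
  expect_true(all(vapply(all_k$scopes, function(s)
    all(s[1, ] == s[2, ]), logical(1))))
  expect_error(fit_clusters(P, k = 9), "exceeds")
})

test_that("reported E equals the brute-force recomputation", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    k <- sample(1:3, 1)
    P <- matrix(runif(n * 2, 0, 100), n)
    fit <- fit_clusters(P, k = k, seed = i)
    expect_equal(fit$E, oracle_E(P, fit$assignment), tolerance = 1e-9)
    expect_equal(fit$E, eq_b_objective(P, fit$assignment), tolerance = 1e-12)
  }
})

test_that("the per-iteration objective trace never increases", {
  set.seed(8)
  for (i in 1:5) {
    P <- matrix(runif(30, 0, 100), 15)
    fit <- fit_clusters(P, k = 3, seed = i, restarts = 1)
    expect_true(all(diff(fit$E_trace) <= 1e-12))
  }
})

test_that("two separated blobs are split as the exhaustive optimum", {
  P <- rbind(
    c(1.0, 2.0), c(2.5, 1.5), c(2.0, 3.0), c(1.5, 2.5),
    c(61.0, 72.0), c(63.5, 70.5), c(62.0, 74.0), c(60.5, 71.0))
  best <- oracle_best_2partition(P)
  fit <- fit_clusters(P, k = 2, seed = 1, restarts = 10)
  # equal objective, and the same bipartition up to label swap
  expect_equal(fit$E, best$E)
  expect_equal(fit$extent, best$extent)
  same <- fit$assignment == fit$assignment[1]
  oracle_same <- best$assignment == best$assignment[1]
  expect_true(identical(same, oracle_same))
  expect_true(all(same[1:4]) && !any(same[5:8]))
})

test_that("profiles report native ranges, soil sets and consistent scopes", {
  scene <- generate_scene(scene_config(n_occ = 80, seed = 2))
  cl <- occurrence_climates(scene)
  norm <- fit_normalization(scene$stack)
  prof <- build_profile(cl, norm, species = "vsp", k = 1, seed = 1)
  td <- tidy(prof)
  for (nm in norm$variable) {
    expect_equal(td$min[td$variable == nm], min(cl[[nm]]))
    expect_equal(td$max[td$variable == nm], max(cl[[nm]]))
  }
  expect_setequal(prof$soil_classes, unique(cl$soil))
  # native ranges and normalized cluster scopes agree under the map
  sc <- prof$clusters$scopes[[1]]
  for (i in seq_along(norm$variable)) {
    nm <- norm$variable[i]
    expect_equal(unname(denormalize_value(sc[1, i], norm, nm)),
                 td$min[td$variable == nm])
    expect_equal(unname(denormalize_value(sc[2, i], norm, nm)),
                 td$max[td$variable == nm])
  }
  # single occurrence: degenerate but valid
  one <- build_profile(cl[1, ], norm, species = "one")
  expect_equal(tidy(one)$min, tidy(one)$max)
  expect_error(build_profile(cl[0, ], norm), "no valid occurrence")
})

test_that("the union of cluster scopes nests inside the profile box", {
  scene <- generate_scene(scene_config(n_occ = 60, seed = 6))
  cl <- occurrence_climates(scene)
  norm <- fit_normalization(scene$stack)
  prof <- build_profile(cl, norm, k = 3, seed = 2)
  td <- prof$ranges
  for (s in prof$clusters$scopes) {
    for (i in seq_along(norm$variable)) {
      nm <- norm$variable[i]
      expect_gte(unname(denormalize_value(s[1, i], norm, nm)) + 1e-9,
                 td$min[td$variable == nm])
      expect_lte(unname(denormalize_value(s[2, i], norm, nm)) - 1e-9,
                 td$max[td$variable == nm])
    }
  }
})

test_that("distance surface matches a per-cell oracle on a small grid", {
  set.seed(17)
  nr <- 12; nc <- 15
  mats <- list(a = matrix(runif(nr * nc, 0, 40), nr),
               b = matrix(runif(nr * nc, -10, 10), nr))
  stack <- make_stack(mats, west = 0, north = nr, dx = 1, dy = 1)
  norm <- fit_normalization(stack)
  occ <- data.frame(a = c(12, 25, 18), b = c(-4, 3, 1))
  prof <- build_profile(occ, norm, k = 2, seed = 3)
  surf <- distance_surface(stack, prof)
  for (r in seq_len(nr)) for (co in seq_len(nc)) {
    p <- c(normalize_value(mats$a[r, co], norm, "a"),
           normalize_value(mats$b[r, co], norm, "b"))
    d_oracle <- min(vapply(prof$clusters$scopes, function(s)
      oracle_point_distance(p, s[1, ], s[2, ]), numeric(1)))
    expect_equal(surf$distance$values[r, co], d_oracle, tolerance = 1e-12)
  }
  expect_error(distance_surface(make_stack(mats[1]), prof), "mismatch")
})

test_that("the distance surface is invariant to cluster order", {
  scene <- generate_scene(scene_config(n_occ = 50, seed = 3))
  cl <- occurrence_climates(scene)
  norm <- fit_normalization(scene$stack)
  prof <- build_profile(cl, norm, k = 3, seed = 5)
  d1 <- distance_surface(scene$stack, prof)$distance$values
  prof$clusters$scopes <- rev(prof$clusters$scopes)
  d2 <- distance_surface(scene$stack, prof)$distance$values
  expect_equal(d1, d2)
})

test_that("the suitability transform honours endpoints, soil and monotonicity", {
  m <- matrix(c(0, 1, 2, 4), 2)
  dist_r <- eco_raster(m, 0, 2, 1, 1)
  soil <- eco_raster(matrix(c(1, 1, 2, 1), 2), 0, 2, 1, 1)
  surf <- structure(list(species = "s", distance = dist_r), class = "eco_surface")
  prof <- list(soil_classes = 1)
  out <- suitability_transform(surf, soil, prof)
  # distance 0 with allowed soil: the 0.999 best-habitat endpoint
  expect_equal(out$suitability$values[1, 1], 0.999)
  expect_equal(out$mask$values[1, 1], 1)
  # strictly decreasing in distance on allowed soil
  expect_true(out$suitability$values[2, 1] < 0.999)
  expect_gt(out$suitability$values[2, 1], out$suitability$values[2, 2])
  # disallowed soil forces zero suitability and an unsuitable mask
  expect_equal(out$suitability$values[1, 2], 0)
  expect_equal(out$mask$values[1, 2], 0)
  # sigma is the median positive distance
  expect_equal(out$sigma, stats::median(c(1, 2, 4)))
})

test_that("a k = 1 mask equals the rectangular-envelope inclusion test", {
  scene <- generate_scene(scene_config(n_occ = 100, seed = 14))
  cl <- occurrence_climates(scene)
  norm <- fit_normalization(scene$stack)
  prof <- build_profile(cl, norm, k = 1, seed = 1)
  surf <- predict_suitability(scene$stack, prof, soil = scene$soil)
  td <- prof$ranges
  inbox <- matrix(TRUE, 40, 40)
  for (i in seq_len(nrow(td))) {
    v <- scene$stack$layers[[td$variable[i]]]$values
    inbox <- inbox & v >= td$min[i] & v <= td$max[i]
  }
  oracle_mask <- (inbox & matrix(scene$soil$values %in% prof$soil_classes,
                                 40)) + 0
  expect_equal(surf$mask$values, oracle_mask)
})

test_that("on a noise-free scene the mask brackets occurrences within the truth", {
  scene <- generate_scene(scene_config(n_occ = 150, seed = 23))
  cl <- occurrence_climates(scene)
  norm <- fit_normalization(scene$stack)
  prof <- build_profile(cl, norm, k = 1, seed = 1)
  surf <- predict_suitability(scene$stack, prof, soil = scene$soil)
  idx <- cell_index(scene$soil, cl$longitude, cl$latitude)
  expect_true(all(surf$mask$values[cbind(idx$row, idx$col)] == 1))
  expect_true(all(surf$mask$values <= scene$truth_mask$values))
})

test_that("fitted envelopes tighten toward the achievable truth as n grows", {
  truth <- true_envelope()
  # the tightest envelope any sample can reach: the value extremes over
  # the truth's own suitable cells (cell values are discrete)
  ref_scene <- generate_scene(scene_config(n_occ = 1, seed = 77), truth)
  suitable <- ref_scene$truth_mask$values == 1
  achievable <- vapply(names(ref_scene$stack$layers), function(nm)
    range(ref_scene$stack$layers[[nm]]$values[suitable]), numeric(2))
  gap_for <- function(n) {
    scene <- generate_scene(scene_config(n_occ = n, seed = 77), truth)
    cl <- occurrence_climates(scene)
    norm <- fit_normalization(scene$stack)
    td <- tidy(build_profile(cl, norm))
    sum(vapply(td$variable, function(nm) {
      w <- max(achievable[2, nm] - achievable[1, nm], 1e-9)
      (td$min[td$variable == nm] - achievable[1, nm]) / w +
        (achievable[2, nm] - td$max[td$variable == nm]) / w
    }, numeric(1)))
  }
  gaps <- c(gap_for(5), gap_for(50), gap_for(400))
  expect_true(all(gaps >= -1e-9))    # fitted interval inside the achievable one
  expect_true(all(diff(gaps) <= 0))  # gap shrinks as n grows
  expect_lt(gaps[3], gaps[1])
})
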