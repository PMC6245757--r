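#' Train/test split of occurrence records
#'
#' Seeded shuffle into a training fraction (default 75%) and the
#' residual test fraction used to examine predictive ability. Sizes
#' are `round(n * frac)` and `n - round(n * frac)`; the parts are
#' disjoint and exhaustive.
#'
#' @param climates Data frame of occurrence climate rows.
#' @param train_frac Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed for the shuffle.
#' @return A list with tibbles `train` and `test` and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_occurrences <- function(climates, train_frac = 0.75, seed = 1L) {
  n <- nrow(climates)
  if (n < 4L) stop("need at least 4 records to split")
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)")
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- round(n * train_frac)
  if (n_train < 1L || n_train >= n)
    stop("split leaves an empty part; adjust train_frac")
  train_idx <- sort(perm[seq_len(n_train)])
  test_idx <- sort(perm[(n_train + 1L):n])
  list(train = tibble::as_tibble(climates[train_idx, ]),
       test = tibble::as_tibble(climates[test_idx, ]),
       train_idx = train_idx, test_idx = test_idx)
}

## Inclusion rate: fraction of rows at range distance 0 from some
## cluster scope of the profile.
inclusion_rate <- function(profile, climates) {
  P <- normalize_values(climates, profile$norm)
  D <- vapply(profile$clusters$scopes, function(s) point_distance(P, s),
              numeric(nrow(P)))
  D <- matrix(D, nrow = nrow(P))
  mean(apply(D, 1L, min) == 0)
}

## Coverage: fraction of the scene's valid cells inside the envelope.
coverage_rate <- function(profile, stack_subset) {
  surf <- distance_surface(stack_subset, profile)
  D <- surf$distance$values
  mean(D[!is.na(D)] == 0)
}

subset_norm <- function(norm, vars) {
  out <- norm[match(vars, norm$variable), ]
  structure(out, class = class(norm),
            new_min = attr(norm, "new_min"), new_max = attr(norm, "new_max"))
}

subset_stack <- function(stack, vars) {
  variable_stack(stack$layers[vars])
}

fit_scored_model <- function(train, test, stack, norm, vars, k, seed,
                             restarts) {
  nm <- subset_norm(norm, vars)
  prof <- build_profile(train[, c(vars), drop = FALSE], nm,
                        species = "jackknife", k = k, seed = seed,
                        restarts = restarts)
  incl <- inclusion_rate(prof, test)
  cov <- coverage_rate(prof, subset_stack(stack, vars))
  list(inclusion = incl, coverage = cov, score = incl - cov)
}

#' Jackknife variable-contribution analysis
#'
#' Reproduces the leave-one-variable-out / single-variable jackknife
#' protocol for ranking the ecological factors that constrain a
#' species' modelled distribution. Occurrence climates are split 75/25;
#' for each variable v an envelope model is fitted on the training rows
#' using only v ("with-only") and using all variables except v
#' ("without"). Each model is scored as test inclusion rate minus scene
#' coverage — the fraction of held-out occurrences inside the fitted
#' envelope, penalized by the fraction of the landscape's valid cells
#' the envelope admits. (Raw inclusion alone cannot rank variables: an
#' envelope only relaxes when a variable is removed, and for continuous
#' values the chance that a held-out point escapes the training range
#' is distribution-free.) The contribution of v is
#' `max(0, score(all) - score(without v))`, normalized to sum to 100.
#'
#' @param stack An `eco_stack` of the climate layers (provides the
#'   normalization statistics and the coverage term).
#' @param climates Occurrence climate tibble (e.g. from
#'   [extract_at_points()]); invalid rows are dropped.
#' @param train_frac Training fraction, default 0.75.
#' @param k,restarts Clustering controls passed to [build_profile()].
#' @param seed Integer seed (drives the split and all cluster fits).
#' @return An object of class `eco_contrib`: a tibble with one row per
#'   variable (`with_only_score`, `without_score`, their inclusion and
#'   coverage components, and `contribution` summing to 100), carrying
#'   the full-model scores as attributes.
#' @export
jackknife_importance <- function(stack, climates, train_frac = 0.75,
                                 k = 1L, seed = 1L, restarts = 10L) {
  if ("valid" %in% names(climates)) climates <- climates[climates$valid, ]
  norm <- fit_normalization(stack)
  vars <- norm$variable
  if (length(vars) < 2L) stop("need at least 2 variables for a jackknife")
  sp <- split_occurrences(climates, train_frac = train_frac, seed = seed)
  full <- fit_scored_model(sp$train, sp$test, stack, norm, vars,
                           k, seed, restarts)
  rows <- purrr::map_dfr(vars, function(v) {
    train_v <- sp$train[[v]]
    if (max(train_v) - min(train_v) <= 0) {
      warning(sprintf("variable '%s' is constant on the training rows; contribution 0", v))
      return(tibble::tibble(
        variable = v, with_only_score = NA_real_, without_score = NA_real_,
        with_only_inclusion = NA_real_, without_inclusion = NA_real_,
        with_only_coverage = NA_real_, without_coverage = NA_real_,
        raw_drop = 0))
    }
    only <- fit_scored_model(sp$train, sp$test, stack, norm, v,
                             k, seed, restarts)
    without <- fit_scored_model(sp$train, sp$test, stack, norm,
                                setdiff(vars, v), k, seed, restarts)
    tibble::tibble(
      variable = v,
      with_only_score = only$score, without_score = without$score,
      with_only_inclusion = only$inclusion,
      without_inclusion = without$inclusion,
      with_only_coverage = only$coverage,
      without_coverage = without$coverage,
      raw_drop = max(0, full$score - without$score))
  })
  total <- sum(rows$raw_drop)
  rows$contribution <- if (total > 0) rows$raw_drop / total * 100
  else rep(100 / nrow(rows), nrow(rows))
  if (total <= 0)
    warning("no variable lowered the model score when removed; contributions set uniform")
  structure(rows,
            class = c("eco_contrib", class(rows)),
            full_score = full$score, full_inclusion = full$inclusion,
            full_coverage = full$coverage, seed = seed,
            train_frac = train_frac)
}

#' @export
glance.eco_contrib <- function(x, ...) {
  tibble::tibble(full_score = attr(x, "full_score"),
                 full_inclusion = attr(x, "full_inclusion"),
                 full_coverage = attr(x, "full_coverage"),
                 top_variable = x$variable[which.max(x$contribution)],
                 seed = attr(x, "seed"))
}
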