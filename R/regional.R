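# Regional-profile extraction and validation statistics: Pearson/Euclidean
# similarity with permutation p-values, and control-vs-state linear
# regressions with and without an intercept.

#' Regional mean profile
#'
#' Arithmetic mean of a volume within each atlas gray-matter region, ordered
#' by label (1..n_regions).
#'
#' @param volume 3-D numeric array on the atlas grid.
#' @param atlas A `phantom_atlas` (or list with integer `labels` and
#'   `n_regions`).
#' @param group_label Optional name attached to the profile.
#' @return Object of class `regional_profile`: `region_ids`, `values`
#'   (umol/g/min), `group_label`.
#' @export
regional_means <- function(volume, atlas, group_label = "") {
  check_volume(volume)
  check_same_grid(volume, atlas$labels, c("volume", "atlas"))
  n <- atlas$n_regions
  lab <- atlas$labels
  sel <- lab > 0
  sums <- vapply(split(volume[sel], lab[sel]), mean, numeric(1))
  ids <- as.integer(names(sums))
  missing <- setdiff(seq_len(n), ids)
  if (length(missing))
    stop(sprintf("atlas label(s) %s have no voxels",
                 paste(missing, collapse = ", ")), call. = FALSE)
  structure(list(region_ids = seq_len(n),
                 values = unname(sums[order(ids)]),
                 group_label = group_label),
            class = "regional_profile")
}

#' @export
print.regional_profile <- function(x, ...) {
  cat(sprintf("regional_profile '%s': %d regions, mean %.4g umol/g/min\n",
              x$group_label, length(x$values), mean(x$values)))
  invisible(x)
}

profile_values <- function(p) {
  if (inherits(p, "regional_profile")) p$values else as.numeric(p)
}

check_same_regions <- function(p, q) {
  if (inherits(p, "regional_profile") && inherits(q, "regional_profile") &&
      !identical(p$region_ids, q$region_ids))
    stop("profiles have different region orderings", call. = FALSE)
  pv <- profile_values(p); qv <- profile_values(q)
  if (length(pv) != length(qv))
    stop("profiles have different lengths", call. = FALSE)
  list(p = pv, q = qv)
}

#' Pearson correlation and Euclidean distance between two profiles
#'
#' @param p,q `regional_profile` objects (or numeric vectors) on one region
#'   ordering.
#' @return List with `pearson_r` (NA, with a warning, if either profile has
#'   zero variance) and `euclidean_d`.
#' @export
profile_similarity <- function(p, q) {
  v <- check_same_regions(p, q)
  d <- sqrt(sum((v$p - v$q)^2))
  if (stats::sd(v$p) == 0 || stats::sd(v$q) == 0) {
    warning("zero-variance profile: correlation undefined", call. = FALSE)
    r <- NA_real_
  } else r <- stats::cor(v$p, v$q)
  list(pearson_r = r, euclidean_d = d)
}

#' Permutation test of profile similarity
#'
#' Permutes the region order of one profile `n_perm` times and reports the
#' percentile of the observed statistics in the permutation null:
#' `p_pearson` is the fraction of permuted correlations at or above the
#' observed correlation, `p_distance` the fraction of permuted distances at
#' or below the observed distance (one-sided in both cases). Under the plain
#' percentile convention a p-value of exactly 0 means no permutation matched
#' or beat the observed statistic; `correction = "add_one"` reports the
#' (k + 1) / (n + 1) variant instead.
#'
#' @param p,q Profiles on one region ordering.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param correction `"none"` (plain percentile, default) or `"add_one"`.
#' @return Object of class `similarity_result`: `pearson_r`, `euclidean_d`,
#'   `p_pearson`, `p_distance`, `n_permutations`.
#' @export
permutation_pvalue <- function(p, q, n_perm = 1000L, seed = 1L,
                               correction = c("none", "add_one")) {
  correction <- match.arg(correction)
  stopifnot(n_perm >= 1)
  v <- check_same_regions(p, q)
  obs <- profile_similarity(v$p, v$q)
  k <- length(v$q)

  perm <- with_seed(seed,
    vapply(seq_len(n_perm), function(i) sample.int(k), integer(k)))
  Q <- matrix(v$q[perm], nrow = k)          # k x n_perm permuted profiles
  r_perm <- as.numeric(stats::cor(v$p, Q))
  d_perm <- sqrt(colSums((Q - v$p)^2))

  tail_p <- sum(r_perm >= obs$pearson_r)
  tail_d <- sum(d_perm <= obs$euclidean_d)
  denom <- n_perm
  if (correction == "add_one") {
    tail_p <- tail_p + 1L; tail_d <- tail_d + 1L; denom <- denom + 1L
  }
  structure(list(pearson_r = obs$pearson_r, euclidean_d = obs$euclidean_d,
                 p_pearson = tail_p / denom, p_distance = tail_d / denom,
                 n_permutations = as.integer(n_perm)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("similarity: r = %.3f (p = %.4g), d = %.4g (p = %.4g), %d permutations\n",
              x$pearson_r, x$p_pearson, x$euclidean_d, x$p_distance,
              x$n_permutations))
  invisible(x)
}

#' Control-vs-state linear regression over regional profiles
#'
#' Regresses the state profile (y) on the control profile (x), either through
#' the origin or with a free intercept. The through-origin coefficient of
#' determination is computed against the uncentred sum of squares
#' `sum(y^2)`, the convention for origin-constrained regression.
#'
#' @param control Control profile (x-axis).
#' @param state State profile (y-axis).
#' @param mode `"through_origin"` or `"free_intercept"`.
#' @return Object of class `regression_result`: `slope`, `intercept`
#'   (exactly 0 in through-origin mode), `r_squared`, `mode`.
#' @export
state_regression <- function(control, state,
                             mode = c("through_origin", "free_intercept")) {
  mode <- match.arg(mode)
  v <- check_same_regions(control, state)
  x <- v$p; y <- v$q
  if (all(x == 0)) stop("all-zero control profile", call. = FALSE)

  if (mode == "through_origin") {
    slope <- sum(x * y) / sum(x^2)
    rss <- sum((y - slope * x)^2)
    r2 <- 1 - rss / sum(y^2)
    intercept <- 0
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- summary(fit)$r.squared
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 mode = mode, n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("regression (%s): slope %.3f, intercept %.4g, R^2 %.3f (n = %d)\n",
              x$mode, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Pairwise similarity matrix across group profiles
#'
#' Builds the group-by-group table with Pearson correlations in the upper
#' triangle and Euclidean distances in the lower triangle.
#'
#' @param profiles Named list of `regional_profile` objects.
#' @return Square numeric matrix with dimnames from the profile names;
#'   diagonal NA.
#' @export
similarity_matrix <- function(profiles) {
  n <- length(profiles)
  stopifnot(n >= 2)
  nm <- names(profiles)
  out <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- profile_similarity(profiles[[i]], profiles[[j]])
    out[i, j] <- s$pearson_r
    out[j, i] <- s$euclidean_d
  }
  out
}
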