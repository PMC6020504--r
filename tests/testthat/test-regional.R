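test_that("regional means reduce correctly and respect linearity", {
  const <- array(0.42, dim(small_atlas$labels))
  prof <- regional_means(const, small_atlas)
  expect_equal(prof$values, rep(0.42, small_atlas$n_regions))

  v <- const
  vox1 <- which(small_atlas$labels == 1)[1:3]
  v[vox1] <- c(1, 2, 3)
  expect_equal(regional_means(v, small_atlas)$values[1],
               mean(c(c(1, 2, 3), rep(0.42, sum(small_atlas$labels == 1) - 3))))

  # profile of a group mean equals the mean of per-subject profiles
  site <- default_site()
  coh <- simulate_cohort(small_reference, small_atlas, state_effect("HAEC"),
                         site, 3, seed = 2)
  p_mean <- regional_means(mean_volume(coh$subjects), small_atlas)$values
  p_each <- rowMeans(vapply(coh$subjects, function(s)
    regional_means(s, small_atlas)$values, numeric(small_atlas$n_regions)))
  expect_equal(p_mean, p_each, tolerance = 1e-12)

  broken <- small_atlas
  broken$labels[broken$labels == 2] <- 1L
  expect_error(regional_means(const, broken), "label\\(s\\) 2")
})

test_that("profile similarity: hand-computed values, symmetry, antisymmetry", {
  s <- profile_similarity(c(1, 2, 3), c(2, 4, 6))
  expect_equal(s$pearson_r, 1)
  expect_equal(s$euclidean_d, sqrt(14))

  p <- rnorm(41); q <- rnorm(41)
  s_pq <- profile_similarity(p, q); s_qp <- profile_similarity(q, p)
  expect_equal(s_pq$pearson_r, s_qp$pearson_r)
  expect_equal(s_pq$euclidean_d, s_qp$euclidean_d)

  centred <- p - mean(p)
  expect_equal(profile_similarity(centred, -centred)$pearson_r, -1)
  expect_warning(profile_similarity(rep(1, 5), c(1, 2, 3, 4, 5)),
                 "zero-variance")
})

test_that("identical profiles give p = 0 under the percentile convention", {
  set.seed(8)
  p <- rnorm(41, 0.3, 0.05)
  res <- permutation_pvalue(p, p, n_perm = 1000, seed = 5)
  expect_equal(res$p_pearson, 0)
  expect_equal(res$p_distance, 0)
  # the corrected variant cannot be zero
  resc <- permutation_pvalue(p, p, n_perm = 1000, seed = 5,
                             correction = "add_one")
  expect_equal(resc$p_pearson, 1 / 1001)
})

test_that("permutation p-values are seed-deterministic and permutation-invariant", {
  set.seed(12)
  p <- rnorm(41); q <- p * 0.8 + rnorm(41, 0, 0.3)
  r1 <- permutation_pvalue(p, q, n_perm = 500, seed = 77)
  r2 <- permutation_pvalue(p, q, n_perm = 500, seed = 77)
  expect_identical(r1, r2)

  # applying one permutation to both profiles leaves the statistics unchanged
  perm <- sample.int(41)
  s0 <- profile_similarity(p, q)
  s1 <- profile_similarity(p[perm], q[perm])
  expect_equal(s1$pearson_r, s0$pearson_r)
  expect_equal(s1$euclidean_d, s0$euclidean_d)
})

test_that("state regressions match their closed forms", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  y <- c(0.12, 0.17, 0.33, 0.38, 0.52)

  to <- state_regression(x, y, "through_origin")
  expect_equal(to$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
  expect_identical(to$intercept, 0)
  expect_equal(to$r_squared, 1 - sum((y - to$slope * x)^2) / sum(y^2),
               tolerance = 1e-12)

  fi <- state_regression(x, y, "free_intercept")
  # normal equations oracle
  xc <- x - mean(x); yc <- y - mean(y)
  expect_equal(fi$slope, sum(xc * yc) / sum(xc^2), tolerance = 1e-12)
  expect_equal(fi$intercept, mean(y) - fi$slope * mean(x), tolerance = 1e-12)

  # suppressing lm's "essentially perfect fit" note for the exact case
  same <- suppressWarnings(state_regression(x, x, "free_intercept"))
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0, tolerance = 1e-12)
  expect_equal(same$r_squared, 1)

  prop <- state_regression(x, 0.8 * x, "through_origin")
  expect_equal(prop$slope, 0.8, tolerance = 1e-12)
  expect_equal(prop$r_squared, 1, tolerance = 1e-12)

  expect_error(state_regression(rep(0, 5), y), "all-zero")
})

test_that("free-intercept regression recovers a known noisy generator", {
  set.seed(21)
  ok <- replicate(100, {
    x <- runif(41, 0.2, 0.45)
    y <- 0.7 * x + 0.04 + rnorm(41, 0, 0.01)
    fi <- state_regression(x, y, "free_intercept")
    fi$slope > 0.6 && fi$slope < 0.8 &&
      fi$intercept > 0.02 && fi$intercept < 0.06
  })
  expect_true(all(ok))
})

test_that("a configured state ladder is recovered by through-origin slopes", {
  # gray-matter factor ladder spanning eyes-open to unresponsive analogues
  factors <- c(1.12, 0.97, 0.92, 0.85, 0.86, 0.64, 0.60, 0.46)
  site <- site_params("ladder", psf_fwhm_mm = 0, noise_sd_counts = 1,
                      subject_cv = 0.05)
  ctrl <- simulate_cohort(small_reference, small_atlas, state_effect("HAEC"),
                          site, 4, seed = 50)
  p_ctrl <- regional_means(mean_volume(ctrl$ground_truth), small_atlas)
  slopes <- vapply(seq_along(factors), function(i) {
    st <- state_effect("s", gm_factor = factors[i], wm_factor = factors[i])
    coh <- simulate_cohort(small_reference, small_atlas, st, site, 4,
                           seed = 50)  # paired subjects
    p_st <- regional_means(mean_volume(coh$ground_truth), small_atlas)
    state_regression(p_ctrl, p_st, "through_origin")$slope
  }, numeric(1))
  expect_true(all(abs(slopes - factors) / factors < 0.05))
  expect_identical(order(slopes), order(factors))
})
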