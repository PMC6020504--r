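test_that("smoothness estimator: white noise reads as sub-voxel, known kernels recovered", {
  set.seed(11)
  d <- c(48, 48, 48)
  mask <- array(TRUE, d)
  noise <- array(rnorm(prod(d)), d)
  est0 <- estimate_fwhm(noise, mask, c(3, 3, 3))
  expect_equal(est0$fwhm_mm, c(0, 0, 0))

  sm8 <- gaussian_smooth(noise, 8, c(3, 3, 3))
  est8 <- estimate_fwhm(sm8, mask, c(3, 3, 3))
  expect_true(all(abs(est8$fwhm_mm - 8) / 8 < 0.15))

  sm12 <- gaussian_smooth(noise, 12, c(3, 3, 3))
  est12 <- estimate_fwhm(sm12, mask, c(3, 3, 3))
  expect_true(all(est12$fwhm_mm > est8$fwhm_mm))

  expect_error(estimate_fwhm(array(1, d), mask, c(3, 3, 3)), "constant")
})

test_that("voxel distributions are proper probability histograms", {
  d <- c(12, 12, 12)
  mask <- array(TRUE, d)

  const <- array(0.7, d)
  h <- voxel_distribution(const, mask, n_bins = 10, range = c(0, 1))
  expect_equal(sum(h$probabilities), 1, tolerance = 1e-9)
  expect_equal(sum(h$probabilities > 0), 1)

  # ten equally frequent values into ten equal bins -> uniform 0.1
  v <- array(rep(0.1 * (1:10), each = 100), c(10, 10, 10))
  hu <- voxel_distribution(v, array(TRUE, c(10, 10, 10)),
                           n_bins = 10, range = c(0.05, 1.05))
  expect_equal(hu$probabilities, rep(0.1, 10), tolerance = 1e-9)

  # out-of-range values are clipped into the end bins, mass preserved
  vr <- array(runif(prod(d), -1, 2), d)
  hc <- voxel_distribution(vr, mask, n_bins = 16, range = c(0, 1))
  expect_equal(sum(hc$probabilities), 1, tolerance = 1e-9)
  expect_gt(hc$n_clipped, 0)

  expect_error(voxel_distribution(const, array(FALSE, d), 10), "empty mask")
})

test_that("Jensen-Shannon divergence matches its definition and bounds", {
  p <- hist_from_p(c(0.5, 0.5))
  q <- hist_from_p(c(0.25, 0.75))
  expect_equal(jensen_shannon(p, p), 0)
  expect_equal(jensen_shannon(p, q),
               jsd_bruteforce(c(0.5, 0.5), c(0.25, 0.75)), tolerance = 1e-12)
  # disjoint supports attain the log(2) bound
  expect_equal(jensen_shannon(hist_from_p(c(1, 0)), hist_from_p(c(0, 1))),
               log(2))
  expect_error(
    jensen_shannon(p, hist_from_p(c(0.5, 0.5), edges = c(0, 2, 4))),
    "mismatched")
})

test_that("identity counts are recovered as a = 1, b = 0 with near-zero divergence", {
  gmwm <- std_atlas$gm_mask | std_atlas$wm_mask
  fit <- fit_site_transform(std_reference, std_reference, gmwm, gmwm,
                            n_bins = 128)
  expect_equal(fit$a_site, 1, tolerance = 0.02)
  expect_lt(abs(fit$b_site), 0.31 * 0.02)
  expect_lt(fit$achieved_jsd, 1e-3)
})

test_that("noise-free counts recover the true transform within 1 per cent", {
  site <- site_params("clean", a_true = 0.0025, b_true = 0.02,
                      psf_fwhm_mm = 0, noise_sd_counts = 0, subject_cv = 0)
  coh <- simulate_cohort(std_reference, std_atlas, state_effect("HAEC"),
                         site, 2, seed = 1)
  gmwm <- std_atlas$gm_mask | std_atlas$wm_mask
  fit <- fit_site_transform(mean_volume(coh$subjects), std_reference,
                            gmwm, gmwm, n_bins = 128)
  expect_lt(abs(fit$a_site - 0.0025) / 0.0025, 0.01)
  expect_lt(abs(fit$b_site - 0.02) / 0.31, 0.01)
})

test_that("rescaling counts rescales the slope and leaves b and the divergence alone", {
  site <- default_site()
  coh <- simulate_cohort(std_reference, std_atlas, state_effect("HAEC"),
                         site, 4, seed = 6)
  mc <- mean_volume(coh$subjects)
  ic <- std_atlas$intracranial_mask
  gmwm <- std_atlas$gm_mask | std_atlas$wm_mask
  f1 <- fit_site_transform(mc, std_reference_acmr, ic, gmwm)
  f3 <- fit_site_transform(mc * 3, std_reference_acmr, ic, gmwm)
  expect_equal(f3$a_site, f1$a_site / 3, tolerance = 1e-3)
  expect_equal(f3$b_site, f1$b_site, tolerance = 0.31 * 0.005)
  expect_equal(f3$achieved_jsd, f1$achieved_jsd, tolerance = 1e-4)
})

test_that("apply_transform is the documented affine map and commutes with averaging", {
  v <- array(100, c(4, 4, 4))
  out <- apply_transform(v, list(a_site = 0.002, b_site = 0.01))
  expect_equal(unique(as.numeric(out)), 0.21)
  expect_identical(apply_transform(v, list(a_site = 1, b_site = 0)), v)

  calib <- list(a_site = 0.0024, b_site = 0.015)
  prof_then <- regional_means(apply_transform(small_reference, calib),
                              small_atlas)$values
  then_prof <- calib$a_site * regional_means(small_reference,
                                             small_atlas)$values +
    calib$b_site
  expect_equal(prof_then, then_prof, tolerance = 1e-12)
})
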