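test_that("atlas satisfies its structural invariants", {
  a <- std_atlas
  sizes <- tabulate(a$labels[a$labels > 0], nbins = 41)
  expect_length(sizes, 41)
  expect_true(all(sizes >= 8))
  # labelled voxels live in the gray mask, masks nest inside the skull
  expect_true(all(a$gm_mask[a$labels > 0]))
  expect_false(any(a$labels > 0 & !a$gm_mask))
  expect_true(all(a$intracranial_mask[a$gm_mask | a$wm_mask]))
  expect_false(any(a$gm_mask & a$wm_mask))
  expect_true(all(a$visual_labels %in% 1:41))
})

test_that("atlas generation is deterministic per seed and fails on tiny grids", {
  a1 <- make_phantom_atlas(c(30, 30, 30), c(3, 3, 3), 10, seed = 5)
  a2 <- make_phantom_atlas(c(30, 30, 30), c(3, 3, 3), 10, seed = 5)
  expect_identical(a1$labels, a2$labels)
  expect_error(make_phantom_atlas(c(10, 10, 10), c(3, 3, 3), 41, seed = 1),
               "cannot host")
})

test_that("a single-region atlas labels the whole cerebral gray shell", {
  a <- make_phantom_atlas(c(24, 24, 24), c(3, 3, 3), 1, seed = 7)
  expect_identical(a$labels > 0, a$gm_mask)
  expect_true(all(a$labels[a$gm_mask] == 1L))
})

test_that("reference map hits the requested tissue levels", {
  flat <- make_reference_map(std_atlas, 0.31, 0.12, regional_cv = 0, seed = 1)
  expect_equal(unique(flat[std_atlas$gm_mask]), 0.31)
  expect_equal(unique(flat[std_atlas$wm_mask]), 0.12)
  expect_true(all(flat[!std_atlas$intracranial_mask] == 0))

  r25 <- make_reference_map(std_atlas, 0.30, 0.12, regional_cv = 0, seed = 1)
  expect_equal(mean(r25[std_atlas$gm_mask]) / mean(r25[std_atlas$wm_mask]),
               2.5, tolerance = 1e-10)
  expect_error(make_reference_map(std_atlas, 0.1, 0.2), "gm_mean > wm_mean")
})

test_that("regional perturbations carry the requested coefficient of variation", {
  cvs <- vapply(1:20, function(s) {
    ref <- make_reference_map(std_atlas, regional_cv = 0.1, seed = 100 + s)
    prof <- regional_means(ref, std_atlas)$values
    sd(prof) / mean(prof)
  }, numeric(1))
  expect_true(all(cvs > 0.05 & cvs < 0.15))
})

test_that("identity site configuration reproduces the reference exactly", {
  site <- site_params("id", a_true = 1, b_true = 0, psf_fwhm_mm = 0,
                      noise_sd_counts = 0, subject_cv = 0)
  coh <- simulate_cohort(small_reference, small_atlas, state_effect("HAEC"),
                         site, 2, seed = 1)
  expect_equal(coh$subjects[[1]], small_reference, ignore_attr = TRUE)
  expect_equal(coh$ground_truth[[1]], small_reference, ignore_attr = TRUE)
})

test_that("the true transform inverts noise-free counts voxelwise (round trip)", {
  site <- site_params("rt", a_true = 0.0025, b_true = 0.02, psf_fwhm_mm = 0,
                      noise_sd_counts = 0, subject_cv = 0.05)
  coh <- simulate_cohort(small_reference, small_atlas, state_effect("HAEC"),
                         site, 3, seed = 9)
  calib <- list(a_site = 0.0025, b_site = 0.02)
  ic <- small_atlas$intracranial_mask
  for (i in 1:3) {
    rec <- apply_transform(coh$subjects[[i]], calib)
    expect_equal(rec[ic], coh$ground_truth[[i]][ic], tolerance = 1e-12)
  }
})

test_that("cohorts are bit-reproducible and state effects scale the gray mean", {
  site <- default_site()
  c1 <- simulate_cohort(small_reference, small_atlas, state_effect("HAEC"),
                        site, 3, seed = 42)
  c2 <- simulate_cohort(small_reference, small_atlas, state_effect("HAEC"),
                        site, 3, seed = 42)
  expect_identical(c1$subjects, c2$subjects)

  # effect monotonicity on the noiseless ground truth, cv = 0
  site0 <- site_params("s", subject_cv = 0, noise_sd_counts = 0)
  gm_means <- vapply(c(0.8, 0.9, 1.0, 1.1), function(f) {
    coh <- simulate_cohort(small_reference, small_atlas,
                           state_effect("x", gm_factor = f), site0, 2,
                           seed = 1)
    mean(coh$ground_truth[[1]][small_atlas$gm_mask])
  }, numeric(1))
  expect_true(all(diff(gm_means) > 0))
  expect_equal(gm_means[1] / gm_means[3], 0.8, tolerance = 1e-12)
})

test_that("all cohort signal stays inside the intracranial mask", {
  site <- default_site()
  coh <- simulate_cohort(small_reference, small_atlas,
                         state_effect("HAEC"), site, 2, seed = 3)
  out <- !small_atlas$intracranial_mask
  for (v in c(coh$subjects, coh$ground_truth))
    expect_true(all(v[out] == 0))
})

test_that("negative noise-free counts are clamped with a warning", {
  # large intercept pushes white-matter counts negative
  site <- site_params("clamp", a_true = 0.0025, b_true = 0.15,
                      psf_fwhm_mm = 0, noise_sd_counts = 0, subject_cv = 0)
  expect_warning(
    coh <- simulate_cohort(small_reference, small_atlas,
                           state_effect("HAEC"), site, 2, seed = 1),
    "clamped")
  expect_true(all(coh$subjects[[1]] >= 0))
})
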