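# Shared fixtures, built once per test run. The standard phantom mirrors the
# analysis grid (48^3 voxels at 3 mm, 41 gray-matter regions); the small
# phantom keeps unit tests fast.

std_atlas <- make_phantom_atlas(c(48L, 48L, 48L), c(3, 3, 3), 41L, seed = 1L)
std_reference <- make_reference_map(std_atlas, gm_mean = 0.31,
                                    wm_mean = 0.12, regional_cv = 0.1,
                                    seed = 2L)
# the reference map as observed by a scanner with a 6.5 mm point spread
std_reference_psf <- 6.5
std_reference_acmr <- masked_smooth(std_reference,
                                    std_atlas$intracranial_mask,
                                    std_reference_psf,
                                    std_atlas$voxel_size_mm)

small_atlas <- make_phantom_atlas(c(24L, 24L, 24L), c(3, 3, 3), 8L, seed = 3L)
small_reference <- make_reference_map(small_atlas, regional_cv = 0.08,
                                      seed = 4L)

default_site <- function(...) {
  site_params(name = "test_site", a_true = 0.0025, b_true = 0.02,
              psf_fwhm_mm = 3.3, noise_sd_counts = 3, subject_cv = 0.05, ...)
}

# build a voxel_histogram directly from a probability vector (unit bins)
hist_from_p <- function(p, edges = seq(0, 1, length.out = length(p) + 1)) {
  structure(list(bin_edges = edges, probabilities = p, n = NA_integer_,
                 n_clipped = 0L),
            class = "voxel_histogram")
}

# independent brute-force JSD straight from the definition (natural log)
jsd_bruteforce <- function(p, q) {
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log(q[i] / m[i])
  }
  s
}
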