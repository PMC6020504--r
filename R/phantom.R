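# Synthetic multi-site brain phantom: an ellipsoidal "brain" with a gray
# shell parcellated into angular-sector regions, a white core, an inferior
# cap standing in for the cerebellum (excluded from calibration masks), and
# cohorts of raw-count images generated from known per-site linear transforms.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Build the phantom atlas
#'
#' Constructs a deterministic ellipsoidal brain phantom: an intracranial
#' ellipsoid holding an inner white-matter core and an outer gray-matter
#' shell, with an inferior cap playing the role of the cerebellum (inside the
#' skull, excluded from the cerebrum masks used for calibration). The
#' cerebral gray shell is partitioned into `n_regions` contiguous labels by
#' latitude band and longitude sector; the labels whose centroids lie most
#' posterior are flagged as "visual cortex".
#'
#' @param grid_shape Integer 3-vector, voxels per axis (default 48^3).
#' @param voxel_size_mm Numeric 3-vector of voxel edge lengths (default 3 mm).
#' @param n_regions Number of gray-matter regions (default 41).
#' @param seed Integer seed; jitters the sector boundary rotation only, so
#'   geometry is reproducible per seed.
#' @param n_visual Number of posterior labels flagged as visual cortex.
#' @return An object of class `phantom_atlas`: integer `labels` volume
#'   (0 = none, 1..n_regions), logical masks `gm_mask`, `wm_mask`,
#'   `intracranial_mask`, `cerebrum_mask`, the `visual_labels` vector and
#'   `voxel_size_mm`.
#' @export
make_phantom_atlas <- function(grid_shape = c(48L, 48L, 48L),
                               voxel_size_mm = c(3, 3, 3),
                               n_regions = 41L, seed = 1L,
                               n_visual = 3L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            all(voxel_size_mm > 0), n_regions >= 1)
  d <- as.integer(grid_shape)

  # normalised coordinates in [-1, 1] per axis, ellipsoid semi-axes at 0.84
  # of the half-extent so the brain clears the grid edge
  ax <- lapply(1:3, function(k) {
    c0 <- (d[k] + 1) / 2
    ((seq_len(d[k]) - c0) / ((d[k] - 1) / 2)) / 0.84
  })
  X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
  Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  r <- sqrt(X^2 + Y^2 + Z^2)

  intracranial <- r <= 1
  # white core radius: shell (gray) volume twice the core volume -> r = 3^(-1/3)
  r_wm <- (1 / 3)^(1 / 3)
  core <- r <= r_wm
  shell <- intracranial & !core
  cerebellum <- intracranial & (Z < -0.62) & (Y < 0)
  cerebrum <- intracranial & !cerebellum
  gm_mask <- shell & cerebrum
  wm_mask <- core & cerebrum

  # partition the cerebral gray shell into latitude bands x longitude sectors
  phi0 <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  n_bands <- max(1L, min(5L, n_regions))
  per_band <- rep(n_regions %/% n_bands, n_bands)
  extra <- n_regions %% n_bands
  if (extra > 0) per_band[seq_len(extra)] <- per_band[seq_len(extra)] + 1L

  idx <- which(gm_mask)
  zq <- stats::quantile(Z[idx], probs = seq(0, 1, length.out = n_bands + 1))
  band <- findInterval(Z[idx], zq, rightmost.closed = TRUE, all.inside = TRUE)
  phi <- (atan2(Y[idx], X[idx]) + phi0) %% (2 * pi)

  labels <- array(0L, d)
  offset <- 0L
  for (b in seq_len(n_bands)) {
    in_band <- band == b
    nb <- per_band[b]
    sec <- findInterval(phi[in_band], seq(0, 2 * pi, length.out = nb + 1),
                        rightmost.closed = TRUE, all.inside = TRUE)
    labels[idx[in_band]] <- offset + as.integer(sec)
    offset <- offset + nb
  }

  sizes <- tabulate(labels[labels > 0], nbins = n_regions)
  if (any(sizes < 8))
    stop(sprintf(paste("grid %s cannot host %d regions with >= 8 voxels each",
                       "(smallest region has %d); enlarge the grid or reduce",
                       "n_regions"),
                 paste(d, collapse = "x"), n_regions, min(sizes)),
         call. = FALSE)

  # posterior (most negative y-centroid) labels act as visual cortex
  ycent <- vapply(seq_len(n_regions),
                  function(l) mean(Y[labels == l]), numeric(1))
  visual <- order(ycent)[seq_len(min(n_visual, n_regions))]

  structure(list(
    labels = labels,
    gm_mask = gm_mask, wm_mask = wm_mask,
    intracranial_mask = intracranial, cerebrum_mask = cerebrum,
    shell_mask = shell, core_mask = core,
    visual_labels = sort(visual),
    n_regions = as.integer(n_regions),
    voxel_size_mm = as.numeric(voxel_size_mm),
    grid_shape = d, seed = as.integer(seed)
  ), class = "phantom_atlas")
}

#' @export
print.phantom_atlas <- function(x, ...) {
  cat(sprintf("phantom_atlas: %s grid, %g mm voxels, %d GM regions\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm[1],
              x$n_regions))
  cat(sprintf("  GM %d vox, WM %d vox, intracranial %d vox; visual labels: %s\n",
              sum(x$gm_mask), sum(x$wm_mask), sum(x$intracranial_mask),
              paste(x$visual_labels, collapse = ", ")))
  invisible(x)
}

#' Generate the reference absolute-CMRglc map
#'
#' Fills the phantom with absolute cerebral glucose metabolic rates
#' (umol/g/min): gray-shell voxels at `gm_mean` times a per-region
#' multiplicative perturbation, white-core voxels at `wm_mean`, zero outside
#' the intracranial mask. The cerebellar shell receives the unperturbed gray
#' level. Defaults reflect the healthy awake eyes-closed condition
#' (GM around 0.31 umol/g/min, 2-3x the white-matter level).
#'
#' @param atlas A `phantom_atlas`.
#' @param gm_mean Gray-matter mean, umol/g/min (> wm_mean).
#' @param wm_mean White-matter mean, umol/g/min (> 0).
#' @param regional_cv Coefficient of variation of per-region multiplicative
#'   perturbations (0 gives a flat gray shell).
#' @param seed Integer seed for the regional perturbations.
#' @return Volume (3-D array, umol/g/min) with `voxel_size_mm` attribute.
#' @export
make_reference_map <- function(atlas, gm_mean = 0.31, wm_mean = 0.12,
                               regional_cv = 0.1, seed = 1L) {
  stopifnot(inherits(atlas, "phantom_atlas"))
  if (!(gm_mean > wm_mean && wm_mean > 0))
    stop("need gm_mean > wm_mean > 0", call. = FALSE)
  stopifnot(regional_cv >= 0)

  fac <- with_seed(seed, stats::rnorm(atlas$n_regions, 1, regional_cv))
  fac <- pmax(fac, 0.2)

  vol <- array(0, atlas$grid_shape)
  vol[atlas$shell_mask] <- gm_mean        # incl. cerebellar shell
  vol[atlas$core_mask] <- wm_mean
  lab <- atlas$labels
  sel <- lab > 0
  vol[sel] <- gm_mean * fac[lab[sel]]
  set_voxel_size(vol, atlas$voxel_size_mm)
}

#' Describe a physiological or clinical state
#'
#' A state is a multiplicative perturbation of the reference metabolism:
#' `gm_factor` scales all gray-shell voxels, `wm_factor` the white core, and
#' `regional_factors` (named by region label) override `gm_factor` for
#' specific regions -- e.g. a congenitally-blind-like state raises the visual
#' labels while slightly lowering the rest. `global_offset` (umol/g/min) is
#' added inside the intracranial mask.
#'
#' @param name State label.
#' @param gm_factor,wm_factor Positive multiplicative factors.
#' @param regional_factors Optional named numeric vector, names in 1..41.
#' @param global_offset Additive offset in umol/g/min.
#' @return Object of class `state_effect`.
#' @export
state_effect <- function(name, gm_factor = 1, wm_factor = 1,
                         regional_factors = NULL, global_offset = 0) {
  stopifnot(gm_factor > 0, wm_factor > 0)
  if (!is.null(regional_factors)) {
    stopifnot(!is.null(names(regional_factors)),
              all(regional_factors > 0))
  }
  structure(list(name = name, gm_factor = gm_factor, wm_factor = wm_factor,
                 regional_factors = regional_factors,
                 global_offset = global_offset),
            class = "state_effect")
}

#' Describe a tomography site
#'
#' Ground-truth acquisition parameters for one simulated PET site. Counts are
#' generated as `counts = (true_qCMRglc - b_true) / a_true + noise`, so that
#' the linear calibration `a_true * counts + b_true` inverts the simulation
#' exactly in the noise-free, blur-free case.
#'
#' @param name Site identifier.
#' @param a_true Positive slope of the count-to-CMRglc transform
#'   (umol/g/min per count).
#' @param b_true Intercept, umol/g/min.
#' @param psf_fwhm_mm Scanner point-spread FWHM in mm (0 = no blur).
#' @param noise_sd_counts Additive Gaussian noise SD in count units.
#' @param subject_cv Coefficient of variation of the per-subject global
#'   lognormal multiplier.
#' @return Object of class `site_params`.
#' @export
site_params <- function(name = "site1", a_true = 0.0025, b_true = 0.02,
                        psf_fwhm_mm = 4, noise_sd_counts = 3,
                        subject_cv = 0.05) {
  stopifnot(a_true > 0, psf_fwhm_mm >= 0, noise_sd_counts >= 0,
            subject_cv >= 0)
  structure(list(name = name, a_true = a_true, b_true = b_true,
                 psf_fwhm_mm = psf_fwhm_mm,
                 noise_sd_counts = noise_sd_counts,
                 subject_cv = subject_cv),
            class = "site_params")
}

apply_state <- function(reference, atlas, state) {
  vol <- reference
  vol[atlas$shell_mask] <- vol[atlas$shell_mask] * state$gm_factor
  vol[atlas$core_mask] <- vol[atlas$core_mask] * state$wm_factor
  if (!is.null(state$regional_factors)) {
    lab <- atlas$labels
    for (nm in names(state$regional_factors)) {
      l <- as.integer(nm)
      sel <- lab == l
      # override, not compound: undo the gray factor first
      vol[sel] <- reference[sel] * state$regional_factors[[nm]]
    }
  }
  if (state$global_offset != 0) {
    ic <- atlas$intracranial_mask
    vol[ic] <- vol[ic] + state$global_offset
  }
  vol
}

#' Simulate a cohort of raw-count images
#'
#' For each subject the noise-free ground truth is the reference map under
#' the state's tissue/region factors, times a per-subject global lognormal
#' multiplier (mean 1, CV `site$subject_cv`), plus the state's global offset.
#' Counts are the inverse site transform of that truth plus additive Gaussian
#' noise, then blurred by the site point-spread function (mask-renormalised
#' Gaussian, so counts stay inside the head). Two calls with the same seed
#' and `n_subjects` reuse the same subject multipliers and noise fields,
#' which is how paired designs (same subjects scanned in two states, as at
#' the sedation site) are simulated.
#'
#' @param reference Reference absolute-CMRglc volume.
#' @param atlas A `phantom_atlas` on the same grid.
#' @param state A `state_effect`.
#' @param site A `site_params`.
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed; cohorts are bit-reproducible per seed.
#' @return Object of class `phantom_cohort` with `subjects` (count volumes),
#'   `ground_truth` (noise-free qCMRglc volumes), site/state descriptors and
#'   the seed.
#' @export
simulate_cohort <- function(reference, atlas, state, site, n_subjects,
                            seed = 1L) {
  stopifnot(inherits(atlas, "phantom_atlas"), inherits(state, "state_effect"),
            inherits(site, "site_params"), n_subjects >= 2)
  check_same_grid(reference, atlas$labels, c("reference", "atlas"))

  state_map <- apply_state(reference, atlas, state)
  ic <- atlas$intracranial_mask
  sdlog <- sqrt(log(1 + site$subject_cv^2))

  res <- with_seed(seed, {
    mult <- exp(stats::rnorm(n_subjects, -sdlog^2 / 2, sdlog))
    subjects <- vector("list", n_subjects)
    truth <- vector("list", n_subjects)
    clamped <- 0L
    for (i in seq_len(n_subjects)) {
      gt <- state_map * mult[i]
      gt[!ic] <- 0
      truth[[i]] <- set_voxel_size(gt, atlas$voxel_size_mm)

      counts <- (gt - site$b_true) / site$a_true
      counts[!ic] <- 0
      neg <- counts < 0 & ic
      if (any(neg)) {
        clamped <- clamped + sum(neg)
        counts[neg] <- 0
      }
      if (site$noise_sd_counts > 0)
        counts[ic] <- counts[ic] +
          stats::rnorm(sum(ic), 0, site$noise_sd_counts)
      if (site$psf_fwhm_mm > 0)
        counts <- masked_smooth(counts, ic, site$psf_fwhm_mm,
                                atlas$voxel_size_mm)
      subjects[[i]] <- set_voxel_size(counts, atlas$voxel_size_mm)
    }
    list(subjects = subjects, truth = truth, mult = mult, clamped = clamped)
  })
  if (res$clamped > 0)
    warning(sprintf("%d noise-free count voxels were negative and clamped to 0",
                    res$clamped), call. = FALSE)

  structure(list(site_id = site$name, state = state$name,
                 subjects = res$subjects, ground_truth = res$truth,
                 subject_multipliers = res$mult,
                 site = site, state_effect = state,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: site '%s', state '%s', %d subjects (seed %d)\n",
              x$site_id, x$state, x$n_subjects, x$seed))
  invisible(x)
}

#' Voxelwise mean of a list of volumes
#'
#' @param volumes List of 3-D arrays on one grid.
#' @return Their voxelwise mean, keeping the first volume's voxel size.
#' @export
mean_volume <- function(volumes) {
  stopifnot(length(volumes) >= 1)
  out <- Reduce(`+`, volumes) / length(volumes)
  attributes(out) <- attributes(volumes[[1]])
  out
}
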