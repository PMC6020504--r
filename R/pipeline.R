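# End-to-end phantom experiment: generate multi-site cohorts, calibrate each
# site against the reference absolute-CMRglc map, extract regional profiles
# and validation statistics, and contrast qCMRglc with GMN t-maps.

#' Default pipeline configuration
#'
#' Canonical study conditions for the phantom experiment: three sites with
#' scanner-like point-spread functions and distinct count-to-CMRglc
#' transforms, each pairing its awake eyes-closed control with one state --
#' eyes-open (global increase), sedation (heterogeneous global decrease,
#' same subjects as its control), and a congenitally-blind-like state
#' (visual regions up, elsewhere slightly down). Thresholds follow the
#' per-condition choices used for the cluster tables (2 for sedation, 1 for
#' eyes-open, 0.5 for the regionally confined state).
#'
#' @param output_dir Directory for tables and serialized outputs.
#' @param master_seed Integer master seed; all stage seeds derive from it.
#' @param ... Overrides for any top-level config entry.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("qcmr_run_"),
                            master_seed = 1L, ...) {
  cfg <- list(
    output_dir = output_dir,
    master_seed = as.integer(master_seed),
    grid_shape = c(48L, 48L, 48L),
    voxel_size_mm = c(3, 3, 3),
    n_regions = 41L,
    gm_mean = 0.31, wm_mean = 0.12, regional_cv = 0.1,
    reference_psf_mm = 6.5,
    n_subjects = 8L,
    n_bins = 128L,
    smoothing_fwhm_mm = 8,
    connectivity = 26L,
    n_permutations = 1000L,
    write_volumes = FALSE,
    sites = list(
      site1 = list(a_true = 0.0031, b_true = 0.035, psf_fwhm_mm = 4.5,
                   noise_sd_counts = 2.5, subject_cv = 0.05,
                   state = "HAEO", paired = FALSE, threshold_t = 1),
      site2 = list(a_true = 0.0025, b_true = 0.02, psf_fwhm_mm = 3.3,
                   noise_sd_counts = 3, subject_cv = 0.05,
                   state = "Sev0.5", paired = TRUE, threshold_t = 2),
      site3 = list(a_true = 0.0021, b_true = 0.012, psf_fwhm_mm = 3.3,
                   noise_sd_counts = 3, subject_cv = 0.05,
                   state = "CB", paired = FALSE, threshold_t = 0.5)
    )
  )
  dots <- list(...)
  cfg <- utils::modifyList(cfg, dots)
  # a user-supplied site list replaces the default wholesale (no merging)
  if ("sites" %in% names(dots)) cfg$sites <- dots$sites
  structure(cfg, class = "pipeline_config")
}

# canonical state catalogue; CB visual factors need the atlas's visual labels
pipeline_state <- function(name, atlas) {
  switch(name,
    HAEC = state_effect("HAEC"),
    HAEO = state_effect("HAEO", gm_factor = 1.12, wm_factor = 1.10),
    `Sev0.5` = state_effect("Sev0.5", gm_factor = 0.85, wm_factor = 0.92),
    CB = {
      rf <- rep(1.15, length(atlas$visual_labels))
      names(rf) <- atlas$visual_labels
      state_effect("CB", gm_factor = 0.97, wm_factor = 0.97,
                   regional_factors = rf)
    },
    stop(sprintf("unknown state '%s'", name), call. = FALSE))
}

#' Calibrate one site against the reference
#'
#' Convenience wrapper for the full calibration route: mean control count
#' image, point-spread matching of the counts toward the reference, and the
#' JSD fit over the standard masks (reference distribution over cerebral
#' GM+WM, transformed counts over intracranial voxels).
#'
#' Point-spread widths come from acquisition metadata by default -- the
#' site's declared scanner resolution and `reference_fwhm_mm` for the
#' reference map -- because on a phantom whose contrast is piecewise
#' anatomical structure, an autocorrelation-based smoothness estimate
#' reflects the anatomy rather than the blur. `psf_source = "estimate"`
#' instead runs [estimate_fwhm()] on both images, the route one would take
#' with real data whose metadata are unavailable.
#'
#' @param control_cohort `phantom_cohort` of the site's control group.
#' @param reference_acmr Reference absolute-CMRglc volume.
#' @param atlas The phantom atlas (provides the masks).
#' @param n_bins Histogram bins.
#' @param control Optimiser settings passed to [fit_site_transform()].
#' @param reference_fwhm_mm Point-spread FWHM of the reference map, mm
#'   (metadata mode).
#' @param psf_source `"metadata"` (default) or `"estimate"`.
#' @return A `site_calibration`.
#' @export
calibrate_site <- function(control_cohort, reference_acmr, atlas,
                           n_bins = 128L, control = list(),
                           reference_fwhm_mm = 6.5,
                           psf_source = c("metadata", "estimate")) {
  psf_source <- match.arg(psf_source)
  ic <- atlas$intracranial_mask
  ref_mask <- atlas$gm_mask | atlas$wm_mask
  mean_counts <- mean_volume(control_cohort$subjects)
  if (psf_source == "metadata") {
    sm_counts <- rep(control_cohort$site$psf_fwhm_mm, 3)
    sm_ref <- rep(reference_fwhm_mm, 3)
  } else {
    sm_counts <- estimate_fwhm(mean_counts, ic, atlas$voxel_size_mm)$fwhm_mm
    sm_ref <- estimate_fwhm(reference_acmr, ic, atlas$voxel_size_mm)$fwhm_mm
  }
  matched <- match_smoothness(mean_counts, sm_counts, sm_ref,
                              atlas$voxel_size_mm, mask = ic)
  fit_site_transform(matched, reference_acmr, fit_mask = ic,
                     ref_mask = ref_mask, n_bins = n_bins, control = control,
                     smoothness_used = list(counts = sm_counts,
                                            reference = sm_ref,
                                            source = psf_source))
}

#' Run one state-vs-control t-map contrast in both analysis modes
#'
#' Subjects' qCMRglc images are smoothed and t-tested (qCMR branch); for the
#' GMN branch each image is first divided by its whole-brain mean, then
#' smoothed and t-tested. Cluster accounting at the state's threshold under
#' the configured connectivity.
#'
#' @param state_qcmr,control_qcmr Lists of per-subject qCMRglc volumes.
#' @param atlas The phantom atlas.
#' @param threshold_t Cluster-forming |t| threshold.
#' @param fwhm_mm Smoothing FWHM in mm (default 8).
#' @param connectivity Cluster connectivity (default 26).
#' @return List with `tmap_qcmr`, `tmap_gmn`, `clusters_qcmr`,
#'   `clusters_gmn`, `comparison`.
#' @export
contrast_state <- function(state_qcmr, control_qcmr, atlas, threshold_t,
                           fwhm_mm = 8, connectivity = 26) {
  ic <- atlas$intracranial_mask
  vs <- atlas$voxel_size_mm
  smooth_all <- function(vols)
    lapply(vols, function(v) masked_smooth(v, ic, fwhm_mm, vs))

  q_state <- smooth_all(state_qcmr)
  q_ctrl <- smooth_all(control_qcmr)
  tm_q <- two_sample_tmap(q_state, q_ctrl, ic, mode = "qCMR")

  g_state <- smooth_all(lapply(state_qcmr, gmn_scale, brain_mask = ic))
  g_ctrl <- smooth_all(lapply(control_qcmr, gmn_scale, brain_mask = ic))
  tm_g <- two_sample_tmap(g_state, g_ctrl, ic, mode = "GMN")

  cl_q <- threshold_clusters(tm_q, threshold_t, connectivity)
  cl_g <- threshold_clusters(tm_g, threshold_t, connectivity)
  list(tmap_qcmr = tm_q, tmap_gmn = tm_g,
       clusters_qcmr = cl_q, clusters_gmn = cl_g,
       comparison = compare_modes(cl_q, cl_g))
}

#' Run the full phantom experiment
#'
#' Sequences the whole analysis: phantom atlas and reference map, per-site
#' control and state cohorts, per-site JSD calibration, qCMRglc maps,
#' regional profiles with similarity/permutation statistics against the
#' reference, control-vs-state regressions (through-origin and free
#' intercept), qCMR and GMN t-maps with cluster accounting, and the
#' mode-comparison table. All outputs are written as provenance-stamped TSV
#' (plus JSON calibrations and the resolved config) under
#' `config$output_dir`; the run is deterministic for a fixed master seed.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with every intermediate object and the paths of
#'   the written tables.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  ms <- config$master_seed

  atlas <- make_phantom_atlas(config$grid_shape, config$voxel_size_mm,
                              config$n_regions,
                              seed = derive_seed(ms, "atlas"))
  ic <- atlas$intracranial_mask
  reference_true <- make_reference_map(atlas, config$gm_mean, config$wm_mean,
                                       config$regional_cv,
                                       seed = derive_seed(ms, "reference"))
  reference_acmr <- masked_smooth(reference_true, ic,
                                  config$reference_psf_mm,
                                  atlas$voxel_size_mm)
  ref_profile <- regional_means(reference_acmr, atlas, "reference")

  # hash the scientific configuration only, not where it is written
  cfg_for_hash <- unclass(config)
  cfg_for_hash$output_dir <- NULL
  provenance <- c(config_hash = sprintf("%08x",
                                        as.integer(fnv1a(deparse(cfg_for_hash)) %% 2147483647)),
                  master_seed = as.character(ms),
                  package = as.character(utils::packageVersion("qcmr")))

  sites <- list()
  profiles <- list(reference = ref_profile)
  perm_rows <- list()
  reg_rows <- list()
  cmp_rows <- list()

  for (site_name in names(config$sites)) {
    sc <- config$sites[[site_name]]
    site <- site_params(site_name, sc$a_true, sc$b_true, sc$psf_fwhm_mm,
                        sc$noise_sd_counts, sc$subject_cv)
    seed_ctrl <- derive_seed(ms, paste0(site_name, "/HAEC"))
    seed_state <- if (isTRUE(sc$paired)) seed_ctrl else
      derive_seed(ms, paste0(site_name, "/", sc$state))

    ctrl <- simulate_cohort(reference_true, atlas,
                            pipeline_state("HAEC", atlas), site,
                            config$n_subjects, seed_ctrl)
    stt <- simulate_cohort(reference_true, atlas,
                           pipeline_state(sc$state, atlas), site,
                           config$n_subjects, seed_state)

    calib <- calibrate_site(ctrl, reference_acmr, atlas, config$n_bins,
                            reference_fwhm_mm = config$reference_psf_mm)
    qc_ctrl <- lapply(ctrl$subjects, apply_transform, calib = calib,
                      mask = ic)
    qc_state <- lapply(stt$subjects, apply_transform, calib = calib,
                       mask = ic)

    prof_ctrl <- regional_means(mean_volume(qc_ctrl), atlas,
                                paste0("HAEC_", site_name))
    prof_state <- regional_means(mean_volume(qc_state), atlas,
                                 paste0(sc$state, "_", site_name))
    profiles[[prof_ctrl$group_label]] <- prof_ctrl
    profiles[[prof_state$group_label]] <- prof_state

    perm <- permutation_pvalue(ref_profile, prof_ctrl,
                               config$n_permutations,
                               seed = derive_seed(ms, paste0(site_name, "/perm")))
    perm_rows[[site_name]] <- data.frame(
      site = site_name, group = prof_ctrl$group_label,
      pearson_r = perm$pearson_r, euclidean_d = perm$euclidean_d,
      p_pearson = perm$p_pearson, p_distance = perm$p_distance)

    for (m in c("through_origin", "free_intercept")) {
      rg <- state_regression(prof_ctrl, prof_state, m)
      reg_rows[[paste(site_name, m)]] <- data.frame(
        site = site_name, state = sc$state, mode = m,
        slope = rg$slope, intercept = rg$intercept, r_squared = rg$r_squared)
    }

    ctr <- contrast_state(qc_state, qc_ctrl, atlas, sc$threshold_t,
                          config$smoothing_fwhm_mm, config$connectivity)
    cmp_rows[[site_name]] <- cbind(
      data.frame(state = sc$state, threshold_t = sc$threshold_t),
      as.data.frame(ctr$comparison))

    sites[[site_name]] <- list(site = site, control = ctrl, state = stt,
                               calibration = calib, contrast = ctr,
                               qcmr_control = qc_ctrl, qcmr_state = qc_state)
    if (isTRUE(config$write_volumes)) {
      write_volume(ctr$tmap_qcmr$values,
                   file.path(config$output_dir,
                             sprintf("tmap_qcmr_%s.nii.gz", site_name)),
                   atlas$voxel_size_mm)
      write_volume(ctr$tmap_gmn$values,
                   file.path(config$output_dir,
                             sprintf("tmap_gmn_%s.nii.gz", site_name)),
                   atlas$voxel_size_mm)
    }
  }

  prof_df <- do.call(cbind, c(list(region = seq_len(config$n_regions)),
                              lapply(profiles, `[[`, "values")))
  paths <- c(
    profiles = write_tsv(as.data.frame(prof_df),
                         file.path(config$output_dir, "profiles.tsv"),
                         provenance),
    similarity = write_tsv(
      as.data.frame(similarity_matrix(profiles)),
      file.path(config$output_dir, "similarity.tsv"), provenance),
    permutation = write_tsv(do.call(rbind, perm_rows),
                            file.path(config$output_dir, "permutation.tsv"),
                            provenance),
    regressions = write_tsv(do.call(rbind, reg_rows),
                            file.path(config$output_dir, "regressions.tsv"),
                            provenance),
    comparison = write_tsv(do.call(rbind, cmp_rows),
                           file.path(config$output_dir, "comparison.tsv"),
                           provenance))

  calib_path <- file.path(config$output_dir, "calibrations.json")
  jsonlite::write_json(
    lapply(sites, function(s)
      list(a_site = s$calibration$a_site, b_site = s$calibration$b_site,
           achieved_jsd = s$calibration$achieved_jsd,
           a_true = s$site$a_true, b_true = s$site$b_true)),
    calib_path, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config),
                       file.path(config$output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(config = config, atlas = atlas,
                 reference_true = reference_true,
                 reference_acmr = reference_acmr,
                 sites = sites, profiles = profiles,
                 tables = paths))
}
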