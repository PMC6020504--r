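# Calibration of site count images to quantified CMRglc (qCMRglc):
# smoothness estimation and matching, voxel-intensity histograms, the
# Jensen-Shannon divergence objective, and the per-site linear fit
# qCMRglc = a_site * counts + b_site.

#' Estimate per-axis image smoothness (Gaussian FWHM)
#'
#' The classical first-difference estimator for Gaussian random fields: along
#' each axis the lag-one autocorrelation inside the mask is
#' `rho = 1 - var(diff) / (2 * var)`; under a Gaussian autocorrelation model
#' induced by smoothing with a Gaussian of standard deviation `s` (voxels),
#' `rho = exp(-1 / (4 s^2))`, which is inverted for `s` and reported as FWHM
#' in mm. Axes whose estimate falls below one voxel (including unsmoothed
#' white noise, where `rho <= 0`) report 0.
#'
#' @param volume 3-D numeric array.
#' @param mask Logical array; at least 100 voxels with nonzero variance.
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @return Object of class `smoothness`: `fwhm_mm`, a nonnegative 3-vector.
#' @export
estimate_fwhm <- function(volume, mask, voxel_size_mm = voxel_size(volume)) {
  check_volume(volume)
  check_same_grid(volume, mask)
  m <- mask != 0
  if (sum(m) < 100)
    stop("smoothness estimation needs >= 100 masked voxels", call. = FALSE)
  v_tot <- stats::var(volume[m])
  if (!is.finite(v_tot) || v_tot <= 0)
    stop("constant volume inside mask: smoothness undefined", call. = FALSE)

  d <- dim(volume)
  fwhm <- numeric(3)
  for (ax in 1:3) {
    # neighbour pairs along this axis with both voxels inside the mask
    n <- d[ax]
    lo <- switch(ax,
      `1` = list(1:(n - 1), TRUE, TRUE), `2` = list(TRUE, 1:(n - 1), TRUE),
      `3` = list(TRUE, TRUE, 1:(n - 1)))
    hi <- switch(ax,
      `1` = list(2:n, TRUE, TRUE), `2` = list(TRUE, 2:n, TRUE),
      `3` = list(TRUE, TRUE, 2:n))
    a <- do.call(`[`, c(list(volume), lo))
    b <- do.call(`[`, c(list(volume), hi))
    ma <- do.call(`[`, c(list(m), lo)) & do.call(`[`, c(list(m), hi))
    dv <- (b - a)[ma]
    if (length(dv) < 50) { fwhm[ax] <- 0; next }
    rho <- 1 - stats::var(dv) / (2 * v_tot)
    if (!is.finite(rho) || rho <= 0) { fwhm[ax] <- 0; next }
    s_vox <- sqrt(-1 / (4 * log(rho)))
    f <- sigma_to_fwhm(s_vox) * voxel_size_mm[ax]
    fwhm[ax] <- if (f < voxel_size_mm[ax]) 0 else f
  }
  structure(list(fwhm_mm = fwhm), class = "smoothness")
}

#' @export
print.smoothness <- function(x, ...) {
  cat(sprintf("smoothness: FWHM = (%.2f, %.2f, %.2f) mm\n",
              x$fwhm_mm[1], x$fwhm_mm[2], x$fwhm_mm[3]))
  invisible(x)
}

#' Smooth a volume so its point-spread function matches a target
#'
#' Applies, per axis, a Gaussian of FWHM `sqrt(target^2 - current^2)`
#' (the quadrature increment); axes already at or above the target pass
#' through untouched. Only the count image is ever smoothed toward the
#' reference, never the reverse.
#'
#' @param volume 3-D numeric array.
#' @param current,target `smoothness` objects (or numeric FWHM 3-vectors/mm).
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @param mask Optional mask for edge-renormalised smoothing inside the head.
#' @return The smoothness-matched volume.
#' @export
match_smoothness <- function(volume, current, target,
                             voxel_size_mm = voxel_size(volume),
                             mask = NULL) {
  cur <- if (inherits(current, "smoothness")) current$fwhm_mm else
    rep_len(as.numeric(current), 3)
  tar <- if (inherits(target, "smoothness")) target$fwhm_mm else
    rep_len(as.numeric(target), 3)
  inc <- sqrt(pmax(tar^2 - cur^2, 0))
  if (all(inc == 0)) return(volume)
  if (is.null(mask)) gaussian_smooth(volume, inc, voxel_size_mm)
  else masked_smooth(volume, mask, inc, voxel_size_mm)
}

#' Normalised voxel-intensity histogram
#'
#' Histogram of masked voxel values over `n_bins` equal-width bins spanning
#' `range`; values outside the range are clipped into the end bins (and
#' counted), so probabilities always sum to one.
#'
#' @param volume 3-D numeric array.
#' @param mask Logical array selecting the voxels to histogram.
#' @param n_bins Number of bins (>= 10).
#' @param range Length-2 numeric; defaults to the masked value range.
#' @return Object of class `voxel_histogram`: `bin_edges` (length
#'   `n_bins + 1`), `probabilities` (sum to 1), `n`, `n_clipped`.
#' @export
voxel_distribution <- function(volume, mask, n_bins = 128L, range = NULL) {
  check_volume(volume)
  check_same_grid(volume, mask)
  stopifnot(n_bins >= 10)
  x <- volume[mask != 0]
  if (length(x) == 0) stop("empty mask: no voxels to histogram", call. = FALSE)
  if (is.null(range)) {
    range <- base::range(x)
    if (diff(range) == 0) range <- range + c(-0.5, 0.5)
  }
  stopifnot(length(range) == 2, range[2] > range[1])
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  h <- bin_probabilities(x, edges)
  structure(list(bin_edges = edges, probabilities = h$p, n = length(x),
                 n_clipped = h$clipped),
            class = "voxel_histogram")
}

# shared binning core: clip out-of-range values into the end bins
bin_probabilities <- function(x, edges) {
  n_bins <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  clipped <- sum(idx < 1L | idx > n_bins)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  list(p = counts / length(x), clipped = clipped)
}

#' Jensen-Shannon divergence between two histograms
#'
#' `JSD(p, q) = KL(p || m) / 2 + KL(q || m) / 2` with `m = (p + q) / 2`,
#' natural logarithm and the convention `0 * log(0 / x) = 0`. Symmetric,
#' nonnegative, zero iff the histograms agree, bounded above by `log(2)`.
#'
#' @param p,q `voxel_histogram` objects on identical bin edges.
#' @return Nonnegative scalar (nats).
#' @export
jensen_shannon <- function(p, q) {
  stopifnot(inherits(p, "voxel_histogram"), inherits(q, "voxel_histogram"))
  if (length(p$bin_edges) != length(q$bin_edges) ||
      max(abs(p$bin_edges - q$bin_edges)) > 1e-12 * max(abs(p$bin_edges), 1))
    stop("histograms have mismatched bin edges", call. = FALSE)
  jsd_vec(p$probabilities, q$probabilities)
}

jsd_vec <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  (kl(p) + kl(q)) / 2
}

#' Fit the per-site linear calibration by JSD minimisation
#'
#' Finds `(a_site, b_site)` minimising the Jensen-Shannon divergence between
#' the voxel-intensity distribution of the reference absolute-CMRglc map
#' (over the cerebral GM+WM mask) and that of `a * counts + b` (over the
#' intracranial mask). `haec_mean_counts` is the across-subject mean count
#' image of the site's awake eyes-closed control group, already
#' smoothness-matched to the reference (see [match_smoothness()]).
#'
#' Bin edges are fixed from the 0.1-99.9 percentile span of the reference
#' distribution (padded 5 per cent) and shared by every objective
#' evaluation. Because the binned objective is piecewise constant at fine
#' scales, the optimiser is a coarse grid over `(a, b)` around a
#' moment-matching start, a zoomed grid, then Nelder-Mead refinement; the
#' best point ever evaluated is returned.
#'
#' @param haec_mean_counts Mean control count volume (smoothness-matched).
#' @param reference_acmr Reference absolute-CMRglc volume, umol/g/min.
#' @param fit_mask Mask over which the transformed counts are histogrammed
#'   (intracranial voxels).
#' @param ref_mask Mask for the reference distribution (cerebral GM+WM,
#'   cerebellum excluded).
#' @param n_bins Histogram bins (default 128).
#' @param control List of optimiser settings: `grid_n` (points per axis,
#'   default 25), `span_a`/`span_b` (relative half-widths of the coarse
#'   grid, defaults 0.5 and 0.3), `zoom` (half-width of the refinement grid,
#'   default 0.06), `reltol` (Nelder-Mead tolerance on the JSD, 1e-6).
#' @param smoothness_used Optional record of the FWHMs involved in matching,
#'   stored in the fit metadata.
#' @return Object of class `site_calibration`: `a_site`, `b_site`,
#'   `achieved_jsd` and `fit_metadata` (bin edges, evaluation count,
#'   smoothness record).
#' @export
fit_site_transform <- function(haec_mean_counts, reference_acmr,
                               fit_mask, ref_mask, n_bins = 128L,
                               control = list(), smoothness_used = NULL) {
  check_volume(haec_mean_counts, "haec_mean_counts")
  check_volume(reference_acmr, "reference_acmr")
  check_same_grid(haec_mean_counts, fit_mask, c("counts", "fit_mask"))
  check_same_grid(reference_acmr, ref_mask, c("reference", "ref_mask"))

  ctl <- utils::modifyList(list(grid_n = 25L, span_a = 0.5, span_b = 0.3,
                                zoom = 0.06, reltol = 1e-6), control)

  ref <- reference_acmr[ref_mask != 0]
  x <- haec_mean_counts[fit_mask != 0]
  if (stats::sd(x) == 0)
    stop("count image is constant inside fit_mask", call. = FALSE)

  qr_ <- stats::quantile(ref, c(0.001, 0.999), names = FALSE)
  pad <- 0.05 * diff(qr_)
  edges <- seq(qr_[1] - pad, qr_[2] + pad, length.out = n_bins + 1)
  p_ref <- bin_probabilities(ref, edges)$p

  n_eval <- 0L
  best <- list(par = c(NA_real_, NA_real_), value = Inf)
  objective <- function(par) {
    if (par[1] <= 0) return(log(2) + 1)  # outside the admissible half-plane
    n_eval <<- n_eval + 1L
    val <- jsd_vec(p_ref, bin_probabilities(par[1] * x + par[2], edges)$p)
    if (val < best$value) best <<- list(par = par, value = val)
    val
  }

  # moment-matching start
  a0 <- stats::sd(ref) / stats::sd(x)
  b0 <- mean(ref) - a0 * mean(x)
  b_scale <- max(abs(mean(ref)), diff(qr_) / 4)

  grid_eval <- function(a_seq, b_seq) {
    for (a in a_seq) for (b in b_seq) objective(c(a, b))
    best
  }

  # stage 1: coarse grid around the moment start
  a_seq <- a0 * seq(1 - ctl$span_a, 1 + ctl$span_a, length.out = ctl$grid_n)
  b_seq <- b0 + b_scale * seq(-ctl$span_b, ctl$span_b,
                              length.out = ctl$grid_n)
  grid_eval(a_seq[a_seq > 0], b_seq)
  if (best$par[1] %in% range(a_seq) && ctl$span_a < 1)
    stop(sprintf("optimiser hit the slope search bound (a = %.4g); widen control$span_a",
                 best$par[1]), call. = FALSE)

  # stage 2: zoomed grid around the coarse optimum
  a_seq <- best$par[1] * seq(1 - ctl$zoom, 1 + ctl$zoom,
                             length.out = ctl$grid_n)
  b_seq <- best$par[2] + b_scale * ctl$zoom *
    seq(-1, 1, length.out = ctl$grid_n)
  grid_eval(a_seq, b_seq)

  # stage 3: simplex polish (objective tracks the best point ever seen)
  opt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                      control = list(reltol = ctl$reltol, maxit = 500,
                                     parscale = c(a0, b_scale)))
  if (best$value <= opt$value) opt <- list(par = best$par, value = best$value)

  if (opt$par[1] <= 0)
    stop("fitted slope a_site <= 0: calibration failed", call. = FALSE)

  structure(list(
    a_site = opt$par[1], b_site = opt$par[2],
    achieved_jsd = opt$value,
    fit_metadata = list(n_bins = as.integer(n_bins), bin_edges = edges,
                        n_eval = n_eval,
                        start = c(a = a0, b = b0),
                        smoothness_used = smoothness_used)
  ), class = "site_calibration")
}

#' @export
print.site_calibration <- function(x, ...) {
  cat(sprintf("site_calibration: a = %.6g, b = %.6g umol/g/min (JSD %.4g nats, %d evaluations)\n",
              x$a_site, x$b_site, x$achieved_jsd, x$fit_metadata$n_eval))
  invisible(x)
}

#' Apply a site calibration to a count volume
#'
#' `qCMRglc = a_site * counts + b_site`, voxelwise, in umol/g/min. The same
#' transform is applied to every subject and state from the site it was
#' fitted on. Negative outputs are preserved but counted in a warning.
#'
#' @param volume Count volume on the scale the calibration was fitted on.
#' @param calib A `site_calibration` (or list with `a_site`, `b_site`).
#' @param mask Optional mask restricting the negativity accounting.
#' @return qCMRglc volume.
#' @export
apply_transform <- function(volume, calib, mask = NULL) {
  check_volume(volume)
  out <- calib$a_site * volume + calib$b_site
  sel <- if (is.null(mask)) out < 0 else out < 0 & mask != 0
  if (any(sel))
    warning(sprintf("%d voxels mapped to negative qCMRglc", sum(sel)),
            call. = FALSE)
  attributes(out) <- attributes(volume)
  out
}

#' Serialise a site calibration to JSON
#'
#' @param calib A `site_calibration`.
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(list(
    a_site = calib$a_site, b_site = calib$b_site,
    achieved_jsd = calib$achieved_jsd,
    n_bins = calib$fit_metadata$n_bins,
    bin_range = range(calib$fit_metadata$bin_edges),
    smoothness_used = calib$fit_metadata$smoothness_used
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
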