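# Group-level image statistics: global mean normalisation, voxelwise
# two-sample t-maps, suprathreshold connected-component clusters, and the
# qCMRglc-vs-GMN comparison metrics.

#' Global mean normalisation (GMN)
#'
#' Divides a volume by its mean over the whole-brain mask, so the output's
#' mask mean is exactly 1. This removes any per-subject global scale factor:
#' `gmn_scale(g * v) == gmn_scale(v)` for any `g > 0` -- the operation that
#' deletes global metabolic effects before group comparison.
#'
#' @param volume 3-D numeric array.
#' @param brain_mask Logical array; its mean of `volume` must be positive.
#' @return Normalised volume (dimensionless).
#' @export
gmn_scale <- function(volume, brain_mask) {
  check_volume(volume)
  check_same_grid(volume, brain_mask, c("volume", "brain_mask"))
  m <- mean(volume[brain_mask != 0])
  if (!is.finite(m) || m <= 0)
    stop(sprintf("whole-brain mask mean is %.4g; GMN undefined", m),
         call. = FALSE)
  out <- volume / m
  attributes(out) <- attributes(volume)
  out
}

#' Voxelwise two-sample t-map
#'
#' Unpaired two-sample Student's t statistic per masked voxel, assuming equal
#' variance (pooled), with sign `mean(A) - mean(B)` and
#' `df = nA + nB - 2`. Smoothing, if any, is the caller's responsibility
#' (smooth first, then test). Voxels with zero pooled variance yield t = 0
#' when the group means also agree and signed infinity otherwise; both kinds
#' are counted in the returned object.
#'
#' @param groupA,groupB Lists of volumes (>= 2 each) on one grid.
#' @param mask Logical analysis mask.
#' @param mode Free-text tag recording the analysis branch ("qCMR" or "GMN").
#' @return Object of class `tmap`: `values` (t volume, 0 outside the mask),
#'   `df`, `mode` (free-text tag), `group_sizes`, `mask`,
#'   `n_zero_variance`.
#' @export
two_sample_tmap <- function(groupA, groupB, mask, mode = "qCMR") {
  nA <- length(groupA); nB <- length(groupB)
  if (nA < 2 || nB < 2)
    stop("both groups need at least 2 subjects", call. = FALSE)
  for (v in c(groupA, groupB)) check_same_grid(v, mask)
  sel <- which(mask != 0)

  A <- vapply(groupA, function(v) v[sel], numeric(length(sel)))
  B <- vapply(groupB, function(v) v[sel], numeric(length(sel)))
  mA <- rowMeans(A); mB <- rowMeans(B)
  ssA <- rowSums((A - mA)^2); ssB <- rowSums((B - mB)^2)
  df <- nA + nB - 2L
  sp2 <- (ssA + ssB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))

  diff <- mA - mB
  t <- diff / se
  zero_var <- se == 0
  # at zero pooled variance the t statistic degenerates: equal means (up to
  # floating-point noise) give 0, a real mean difference gives signed infinity
  tiny <- abs(diff) <= 1e-8 * pmax(abs(mA), abs(mB))
  t[zero_var & tiny] <- 0
  sgn <- zero_var & !tiny
  t[sgn] <- sign(diff[sgn]) * Inf

  vol <- array(0, dim(mask))
  vol[sel] <- t
  structure(list(values = vol, df = df, mode = mode,
                 group_sizes = c(nA, nB), mask = mask != 0,
                 n_zero_variance = sum(zero_var)),
            class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("tmap (%s): df = %d, groups %d vs %d, t range [%.3g, %.3g]\n",
              x$mode, x$df, x$group_sizes[1], x$group_sizes[2],
              min(v), max(v)))
  invisible(x)
}

neighbour_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = man == 1, "18" = man >= 1 & man <= 2, "26" = man >= 1,
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  off[keep, , drop = FALSE]
}

#' Label connected components of a logical volume
#'
#' Breadth-first labelling under 6-, 18- or 26-neighbour connectivity.
#'
#' @param x Logical 3-D array.
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners, default).
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(x, connectivity = 26) {
  stopifnot(is.array(x), length(dim(x)) == 3)
  d <- dim(x)
  off <- neighbour_offsets(connectivity)

  inset <- x != 0
  labels <- array(0L, d)
  todo <- which(inset)
  lab <- 0L
  for (s in seq_along(todo)) {
    if (labels[todo[s]] != 0L) next
    lab <- lab + 1L
    frontier <- todo[s]
    labels[frontier] <- lab
    while (length(frontier)) {
      fc <- arrayInd(frontier, d)
      # expand: every frontier voxel x every offset
      nb <- fc[rep(seq_len(nrow(fc)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(fc)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * d[1] +
                      (nb[, 3] - 1L) * d[1] * d[2])
      lin <- lin[inset[lin] & labels[lin] == 0L]
      labels[lin] <- lab
      frontier <- lin
    }
  }
  labels
}

#' Suprathreshold cluster accounting for a t-map
#'
#' Counts connected components of `{t > +threshold}` (positive clusters) and
#' `{t < -threshold}` (negative clusters) inside the analysis mask, reporting
#' sizes in voxels and as a percentage of mask voxels.
#'
#' @param tmap A `tmap` (or plain t volume).
#' @param threshold_t Positive threshold on |t|.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param mask Analysis mask; defaults to the t-map's own mask.
#' @return Object of class `cluster_summary`: `threshold_t`, `connectivity`,
#'   `p_count`, `n_count`, `clusters` (data frame: sign, size_voxels,
#'   pct_mask), `mask_voxels`.
#' @export
threshold_clusters <- function(tmap, threshold_t, connectivity = 26,
                               mask = NULL) {
  stopifnot(threshold_t > 0)
  if (inherits(tmap, "tmap")) {
    vol <- tmap$values
    if (is.null(mask)) mask <- tmap$mask
  } else {
    vol <- tmap
    if (is.null(mask)) mask <- array(TRUE, dim(vol))
  }
  check_same_grid(vol, mask, c("tmap", "mask"))
  m <- mask != 0
  n_mask <- sum(m)

  summarise_sign <- function(sel, sgn) {
    lab <- label_components(sel & m, connectivity)
    k <- max(lab)
    if (k == 0) return(NULL)
    sizes <- tabulate(lab[lab > 0], nbins = k)
    data.frame(sign = sgn, size_voxels = sizes,
               pct_mask = 100 * sizes / n_mask)
  }
  pos <- summarise_sign(vol > threshold_t, "positive")
  neg <- summarise_sign(vol < -threshold_t, "negative")
  clusters <- rbind(pos, neg)
  if (is.null(clusters))
    clusters <- data.frame(sign = character(), size_voxels = integer(),
                           pct_mask = numeric())
  structure(list(threshold_t = threshold_t,
                 connectivity = as.integer(connectivity),
                 p_count = if (is.null(pos)) 0L else nrow(pos),
                 n_count = if (is.null(neg)) 0L else nrow(neg),
                 clusters = clusters, mask_voxels = n_mask),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("clusters at |t| > %g (%d-connectivity): P = %d, N = %d (mask %d vox)\n",
              x$threshold_t, x$connectivity, x$p_count, x$n_count,
              x$mask_voxels))
  if (nrow(x$clusters))
    print(transform(x$clusters, pct_mask = round(pct_mask, 2)),
          row.names = FALSE)
  invisible(x)
}

#' Compare qCMRglc and GMN cluster summaries
#'
#' Derived metrics contrasting the two analysis modes: total cluster counts
#' `T = P + N` per mode, and the positive/negative excesses of the GMN mode,
#' `D_P = P_GMN - P_qCMR` and `D_N = N_GMN - N_qCMR`. Positive excesses mean
#' the GMN analysis fragmented a unidirectional global change into
#' bidirectional regional clusters.
#'
#' @param qcmr_summary,gmn_summary `cluster_summary` objects computed at the
#'   same threshold and connectivity.
#' @return Object of class `mode_comparison`: `p_qcmr`, `n_qcmr`, `p_gmn`,
#'   `n_gmn`, `t_qcmr`, `t_gmn`, `d_p`, `d_n`.
#' @export
compare_modes <- function(qcmr_summary, gmn_summary) {
  stopifnot(inherits(qcmr_summary, "cluster_summary"),
            inherits(gmn_summary, "cluster_summary"))
  if (qcmr_summary$threshold_t != gmn_summary$threshold_t)
    stop("cluster summaries were computed at different thresholds",
         call. = FALSE)
  if (qcmr_summary$connectivity != gmn_summary$connectivity)
    stop("cluster summaries use different connectivities", call. = FALSE)
  structure(list(
    p_qcmr = qcmr_summary$p_count, n_qcmr = qcmr_summary$n_count,
    p_gmn = gmn_summary$p_count, n_gmn = gmn_summary$n_count,
    t_qcmr = qcmr_summary$p_count + qcmr_summary$n_count,
    t_gmn = gmn_summary$p_count + gmn_summary$n_count,
    d_p = gmn_summary$p_count - qcmr_summary$p_count,
    d_n = gmn_summary$n_count - qcmr_summary$n_count,
    threshold_t = qcmr_summary$threshold_t
  ), class = "mode_comparison")
}

#' @export
print.mode_comparison <- function(x, ...) {
  cat(sprintf("mode comparison at |t| > %g:\n", x$threshold_t))
  cat(sprintf("  qCMR: P = %d, N = %d (T = %d); GMN: P = %d, N = %d (T = %d)\n",
              x$p_qcmr, x$n_qcmr, x$t_qcmr, x$p_gmn, x$n_gmn, x$t_gmn))
  cat(sprintf("  D_P = %d, D_N = %d\n", x$d_p, x$d_n))
  invisible(x)
}

#' @export
as.data.frame.mode_comparison <- function(x, ...) {
  data.frame(P_qCMR = x$p_qcmr, N_qCMR = x$n_qcmr,
             P_GMN = x$p_gmn, N_GMN = x$n_gmn,
             T_qCMR = x$t_qcmr, T_GMN = x$t_gmn,
             D_P = x$d_p, D_N = x$d_n)
}
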