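# Evaluation suite: ASL CBF quantification, mask overlap (Dice, Hausdorff),
# perfusion SNR / temporal SNR, and field-map correlation.

#' ASL quantification constants
#'
#' Defaults are the standard single-compartment pCASL values: blood T1
#' 1.65 s, labeling efficiency 0.68, brain-blood partition coefficient
#' 0.9 ml/g, post-labeling delay 1.5 s, labeling duration 1.8 s.
#'
#' @param t1_blood longitudinal relaxation time of blood (s)
#' @param alpha labeling efficiency (0 < alpha <= 1)
#' @param lam brain-blood partition coefficient (ml/g)
#' @param pld post-labeling delay (s)
#' @param tau labeling duration (s)
#' @return an object of class `"cbf_params"`
#' @export
cbf_params <- function(t1_blood = 1.65, alpha = 0.68, lam = 0.9,
                       pld = 1.5, tau = 1.8) {
  stopifnot(t1_blood > 0, alpha > 0, alpha <= 1, lam > 0, pld > 0, tau > 0)
  structure(list(t1_blood = t1_blood, alpha = alpha, lam = lam,
                 pld = pld, tau = tau), class = "cbf_params")
}

#' Voxelwise cerebral blood flow from an ASL difference image
#'
#' Single-compartment pCASL quantification:
#' `CBF = (dM/M0) * 6000 * lam * exp(PLD/T1b) /
#'        (2 * alpha * T1b * (1 - exp(-tau/T1b)))` in ml/100 g/min.
#' Voxels with nonpositive `m0` are returned as `NA` (flagged invalid).
#'
#' @param delta_m label/control difference image (control - label)
#' @param m0 equilibrium magnetization image
#' @param p a [cbf_params()]
#' @return CBF array in ml/100 g/min
#' @export
cbf_map <- function(delta_m, m0, p = cbf_params()) {
  stopifnot(inherits(p, "cbf_params"))
  scale <- 6000 * p$lam * exp(p$pld / p$t1_blood) /
    (2 * p$alpha * p$t1_blood * (1 - exp(-p$tau / p$t1_blood)))
  out <- delta_m / m0 * scale
  out[m0 <= 0] <- NA_real_
  out
}

#' Dice overlap coefficient of two masks
#'
#' @param a,b logical masks of the same shape, not both empty
#' @return `2|A intersect B| / (|A| + |B|)` in `[0, 1]`
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) stop("both masks are empty")
  2 * sum(a & b) / (na + nb)
}

# Boundary voxels: mask voxels 6-adjacent (4-adjacent in 2D) to background.
mask_boundary <- function(mask) {
  m <- as_vol(mask)
  bg_dil <- grow_step(!m, array(TRUE, dim(m)))
  b <- m & bg_dil
  restore_dim(b, mask)
}

boundary_coords <- function(mask) {
  m <- as_vol(mask_boundary(mask))
  idx <- which(m)
  d <- dim(m)
  cbind((idx - 1L) %% d[1] + 1L,
        ((idx - 1L) %/% d[1]) %% d[2] + 1L,
        (idx - 1L) %/% (d[1] * d[2]) + 1L)
}

#' Symmetric Hausdorff distance between two masks (voxels)
#'
#' Maximum of the two directed Hausdorff distances between the boundary
#' voxel coordinates (Euclidean; boundaries from the 6-connectivity
#' erosion difference).
#'
#' @param a,b nonempty logical masks of the same shape
#' @return distance in voxels
#' @export
hausdorff <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  if (!any(a) || !any(b)) stop("masks must be nonempty")
  pa <- boundary_coords(a)
  pb <- boundary_coords(b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
  d2 <- pmax(d2, 0)
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

# Mean perfusion-weighted (control - label) image of a series.
perfusion_weighted <- function(series) {
  stopifnot(inherits(series, "perfusion_series"))
  dm <- series$control - series$label
  apply(dm, 1:3, mean)
}

#' Spatial perfusion SNR
#'
#' Mean gray-matter perfusion signal divided by the background standard
#' deviation.
#'
#' @param perf perfusion-weighted image (e.g. mean control - label)
#' @param gm,bg nonempty, disjoint gray-matter and background masks
#' @return scalar SNR
#' @export
perfusion_snr <- function(perf, gm, bg) {
  perf <- as_vol(perf); gm <- as_vol(gm); bg <- as_vol(bg)
  stopifnot(any(gm), any(bg), !any(gm & bg))
  s <- stats::sd(perf[bg])
  if (s == 0) stop("zero-variance background: SNR undefined")
  mean(perf[gm]) / s
}

#' Temporal perfusion SNR
#'
#' Mean over gray matter of the per-voxel temporal mean divided by the
#' temporal standard deviation of the pairwise control - label series.
#'
#' @param series a `perfusion_series`
#' @param gm nonempty gray-matter mask
#' @return scalar tSNR
#' @export
perfusion_tsnr <- function(series, gm) {
  stopifnot(inherits(series, "perfusion_series"))
  dm <- series$control - series$label
  if (dim(dm)[4] < 3L) stop("need at least 3 time points")
  gm <- as_vol(gm)
  stopifnot(any(gm))
  tm <- apply(dm, 1:3, mean)
  ts <- apply(dm, 1:3, stats::sd)
  if (any(ts[gm] == 0)) stop("zero temporal variance in gray matter")
  mean(tm[gm] / ts[gm])
}

#' Pearson correlation of two field maps over a region of interest
#'
#' @param f1,f2 [field_map()] objects (or bare arrays) on the same grid
#' @param roi nonempty logical mask
#' @return Pearson r
#' @export
fieldmap_correlation <- function(f1, f2, roi) {
  v1 <- if (inherits(f1, "field_map")) f1$values else f1
  v2 <- if (inherits(f2, "field_map")) f2$values else f2
  stopifnot(identical(dim(v1), dim(v2)), any(roi))
  x <- v1[roi]; y <- v2[roi]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance inside the ROI")
  stats::cor(x, y)
}

#' In-mask RMSE between two field maps, in displacement voxels
#'
#' Root-mean-square field difference over `roi`, converted to PE-axis
#' displacement with the total readout time.
#'
#' @inheritParams fieldmap_correlation
#' @param params an [acq_params()]
#' @return RMSE in voxels
#' @export
fieldmap_rmse_voxels <- function(f1, f2, roi, params) {
  v1 <- if (inherits(f1, "field_map")) f1$values else f1
  v2 <- if (inherits(f2, "field_map")) f2$values else f2
  sqrt(mean(((v1[roi] - v2[roi]) * params$total_readout_time)^2))
}

#' Centered slice selection along the partition axis
#'
#' Indices of the `width` (default 5) slices centred in a stack of
#' `n_slices`, the slab used for slice-restricted evaluation.
#'
#' @param n_slices number of slices in the stack
#' @param width number of central slices to select
#' @return integer vector of slice indices
#' @export
center_slices <- function(n_slices, width = 5L) {
  width <- min(width, n_slices)
  start <- (n_slices - width) %/% 2L + 1L
  start:(start + width - 1L)
}
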