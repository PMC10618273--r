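# Field-map estimation from a single centric k-space: split with the
# shared centre line, POCS-complete both halves, then iterate automatic
# brain masking + uniformity correction around the reversed-polarity
# estimator.  The blip-down mask comes from dilation on the first pass (no
# field information yet) and from warping the blip-up mask by twice the
# displacement afterwards; the smoothing width is the constant high value
# on all but the last pass and location-dependent on the last.

#' Control settings for the iterative estimation procedure
#'
#' The defaults reproduce the full procedure; the switches expose the
#' ablation variants (POCS only, uniformity correction with
#' dilation-based masking, iterative masking with constant sigma, and the
#' full location-dependent correction).
#'
#' @param n_iterations number of masking/correction/estimation passes
#'   (default 3)
#' @param uniformity apply masking + uniformity correction at all
#'   (`FALSE` = POCS-only ablation, a single estimator call on the raw
#'   POCS magnitudes)
#' @param masking `"iterative"` (warp the blip-up mask with the current
#'   field after the first pass) or `"dilation"` (always use the dilated
#'   blip-up mask)
#' @param final_sigma `"location_dependent"` or `"constant"` smoothing
#'   width on the final pass
#' @param dilate_radius radius of the triangular structuring element used
#'   for the first-pass blip-down mask (default 2)
#' @param pocs_iter,pocs_tol POCS completion settings
#' @return an object of class `"estimation_control"`
#' @export
estimation_control <- function(n_iterations = 3L, uniformity = TRUE,
                               masking = c("iterative", "dilation"),
                               final_sigma = c("location_dependent",
                                               "constant"),
                               dilate_radius = 2L,
                               pocs_iter = 50L, pocs_tol = 1e-6) {
  masking <- match.arg(masking)
  final_sigma <- match.arg(final_sigma)
  stopifnot(n_iterations >= 1L)
  structure(list(n_iterations = as.integer(n_iterations),
                 uniformity = uniformity, masking = masking,
                 final_sigma = final_sigma,
                 dilate_radius = as.integer(dilate_radius),
                 pocs_iter = as.integer(pocs_iter), pocs_tol = pocs_tol),
            class = "estimation_control")
}

#' Estimate the B0 field map from a single centric EPI k-space
#'
#' Runs the full estimation chain: centre-line-sharing split, POCS
#' completion of both halves, and the iterative masking / uniformity
#' correction procedure around [estimate_field_topup()].
#'
#' @param k a centric [kspace()]
#' @param topup_opts a [topup_options()]
#' @param control an [estimation_control()]
#' @return list with elements `field` (a [field_map()]), `mask_up`,
#'   `mask_down` (final masks, `NULL` for the POCS-only variant),
#'   `n_estimations` (number of estimator invocations), and `control`
#' @export
estimate_field_cenepi <- function(k, topup_opts = topup_options(),
                                  control = estimation_control()) {
  stopifnot(inherits(k, "kspace"))
  params <- k$params
  halves <- split_for_estimation(k)
  up <- Mod(pocs_reconstruct(halves$k_up, control$pocs_iter, control$pocs_tol))
  down <- Mod(pocs_reconstruct(halves$k_down, control$pocs_iter,
                               control$pocs_tol))
  if (!control$uniformity) {
    field <- estimate_field_topup(up, down, params, topup_opts)
    return(list(field = field, mask_up = NULL, mask_down = NULL,
                n_estimations = 1L, control = control))
  }
  field <- NULL
  mask_up <- mask_down <- NULL
  n_est <- 0L
  for (i in seq_len(control$n_iterations)) {
    mask_up <- otsu_mask(up)
    mask_down <- if (i == 1L || control$masking == "dilation") {
      dilate_mask(mask_up, control$dilate_radius, direction = "both",
                  pe_axis = params$pe_axis)
    } else {
      warp_mask(mask_up, field, factor = 2, params)
    }
    if (!any(mask_down))
      stop("blip-down mask collapsed at iteration ", i,
           " (field-driven warp emptied the mask)")
    mode <- if (i == control$n_iterations &&
                control$final_sigma == "location_dependent")
      "location_dependent" else "constant"
    uc_up <- uniformity_correct(up, mask_up, sigma_field(mask_up, mode))
    uc_down <- uniformity_correct(down, mask_down, sigma_field(mask_down, mode))
    field <- estimate_field_topup(uc_up, uc_down, params, topup_opts)
    n_est <- n_est + 1L
  }
  list(field = field, mask_up = mask_up, mask_down = mask_down,
       n_estimations = n_est, control = control)
}

#' B0 field map from a double-echo GRE pair
#'
#' The reference method: `f = Arg(echo2 * Conj(echo1)) / (2 * pi *
#' (te2 - te1))` Hz, exact (to machine precision) wherever
#' `|f| < 1 / (2 * dTE)`; beyond that the phase wraps and the estimate
#' aliases (no unwrapping is attempted).  Voxels where either echo has zero
#' magnitude are flagged invalid in the returned `valid` mask.
#'
#' @param echo1,echo2 complex GRE images on the same grid
#' @param te1_s,te2_s echo times in seconds, `te2_s > te1_s`
#' @return a [field_map()] with provenance `"gre"` and an extra `valid`
#'   logical element
#' @export
gre_fieldmap <- function(echo1, echo2, te1_s = 4.92e-3, te2_s = 7.38e-3) {
  if (te2_s <= te1_s) stop("te2_s must exceed te1_s")
  stopifnot(identical(dim(echo1), dim(echo2)))
  f <- Arg(echo2 * Conj(echo1)) / (2 * pi * (te2_s - te1_s))
  valid <- Mod(echo1) > 0 & Mod(echo2) > 0
  f[!valid] <- 0
  fm <- field_map(f, provenance = "gre")
  fm$valid <- valid
  fm
}
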