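# Splitting a single centric k-space into blip-up / blip-down partial
# k-spaces, and POCS partial-Fourier completion of the halves.
#
# Two center-line conventions are used downstream:
#   * estimation split  — the DC row is included in BOTH halves, balancing
#     the signal intensity of the two field-mapping inputs;
#   * correction split  — the DC row goes only to the blip-up half, so the
#     two halves are a disjoint partition of the acquired samples and sum
#     back to the source k-space.

# Number of acquired rows below DC: m = round((pf - 0.5) * N_pe).
pf_lower_extent <- function(params) {
  n_pe <- params$matrix_shape[params$pe_axis]
  as.integer(round((params$partial_fourier - 0.5) * n_pe))
}

check_centric_source <- function(k) {
  stopifnot(inherits(k, "kspace"))
  if (!is_centric(k$params))
    stop("splitting requires a centric trajectory")
  ctr <- dc_index(length(k$acquired_mask))
  if (!k$acquired_mask[ctr]) stop("center PE row was not acquired")
  ctr
}

split_rows <- function(k, down_includes_center) {
  ctr <- check_centric_source(k)
  n_pe <- length(k$acquired_mask)
  m <- pf_lower_extent(k$params)
  up_rows <- ctr:n_pe
  down_top <- if (down_includes_center) ctr else ctr - 1L
  down_rows <- if (down_top >= ctr - m) (ctr - m):down_top else integer(0)
  list(up = up_rows, down = down_rows)
}

make_half <- function(k, rows) {
  n_pe <- length(k$acquired_mask)
  mask <- rep(FALSE, n_pe)
  mask[rows] <- TRUE
  mask <- mask & k$acquired_mask
  data <- zero_unacquired(k$data, mask, k$params$pe_axis)
  kspace(data, mask, k$params)
}

#' Split a centric k-space for field-map estimation
#'
#' The blip-up half keeps PE rows from DC upward; the blip-down half keeps
#' the acquired rows below DC *plus the DC row itself*, which was scanned
#' first and is unaffected by any phase-encode blip — including it in both
#' halves balances the signal intensity of the two estimation inputs.
#' Both outputs are zero-filled to the full matrix.
#'
#' @param k a centric [kspace()]
#' @return list with [kspace()] elements `k_up` and `k_down`
#' @export
split_for_estimation <- function(k) {
  r <- split_rows(k, down_includes_center = TRUE)
  list(k_up = make_half(k, r$up), k_down = make_half(k, r$down))
}

#' Split a centric k-space for distortion correction
#'
#' The DC row is assigned only to the blip-up half; the halves are disjoint
#' and sum exactly back to the source k-space.  Unacquired samples are
#' simply zero-filled (no POCS at the correction stage).
#'
#' @param k a centric [kspace()]
#' @return list with [kspace()] elements `k_up` and `k_down`
#' @export
split_for_correction <- function(k) {
  r <- split_rows(k, down_includes_center = FALSE)
  list(k_up = make_half(k, r$up), k_down = make_half(k, r$down))
}

#' Low-resolution phase reference from the symmetric centre band
#'
#' Phase of the image reconstructed from the Hann-windowed band of
#' `2*m + 1` PE rows around DC.  Used as the POCS phase constraint; for a
#' single centric k-space the band around DC is genuinely acquired (up to
#' the partial-Fourier limit), so the same reference serves both halves
#' after splitting.
#'
#' @param k a [kspace()]
#' @param band_halfwidth half-width `m` of the band in PE rows; default is
#'   the acquired extent below DC
#' @return real array of phase values (radians)
#' @export
lowres_phase <- function(k, band_halfwidth = NULL) {
  stopifnot(inherits(k, "kspace"))
  pe <- k$params$pe_axis
  n_pe <- length(k$acquired_mask)
  ctr <- dc_index(n_pe)
  if (is.null(band_halfwidth)) band_halfwidth <- pf_lower_extent(k$params)
  m <- as.integer(band_halfwidth)
  if (m < 1L) stop("band_halfwidth must be >= 1")
  band_rows <- max(1L, ctr - m):min(n_pe, ctr + m)
  keep <- rep(FALSE, n_pe); keep[band_rows] <- TRUE
  kb <- zero_unacquired(k$data, keep, pe)
  w <- rep(0, n_pe)
  w[band_rows] <- 0.5 * (1 + cos(pi * (band_rows - ctr) / (m + 1)))
  warr <- pe_broadcast(w, dim(kb), pe)
  Arg(ifftc(kb * warr))
}

# Broadcast a per-PE-row vector to an array shape.
pe_broadcast <- function(w, d, pe_axis) {
  array(rep(w, each = prod(d[seq_len(pe_axis - 1L)])), d)
}

# Smoothed phase of a complex image (real and imaginary parts filtered
# separately): the adaptive low-resolution phase estimate used by POCS.
smoothed_phase <- function(x, sigma) {
  Arg(gaussian_smooth(Re(x), sigma) + 1i * gaussian_smooth(Im(x), sigma))
}

#' POCS partial-Fourier reconstruction
#'
#' Projection-onto-convex-sets completion of a partial k-space.
#' Iterations alternate (i) the phase projection
#' `x -> Re(x * exp(-i*phi)) * exp(i*phi)` — the orthogonal projection onto
#' images whose phase matches the low-resolution reference `phi` — and
#' (ii) the data-consistency projection, which restores all acquired
#' samples exactly.  The reference is either supplied (`phase_ref`) or
#' estimated adaptively as the Gaussian-smoothed phase of the current
#' iterate, which preserves each half's own geometry even when the object
#' carries substantial off-resonance phase (a fixed Hermitian-band
#' reference would drag a one-sided reconstruction toward zero phase).
#' The loop ends on the data-consistency step, so the transform of the
#' output matches the input on acquired rows to floating-point precision.
#'
#' @param k_partial a [kspace()] whose acquired rows include DC and at
#'   least one row on one side of it
#' @param n_iter maximum number of iterations (default 50; the adaptive
#'   phase estimate converges more slowly than fixed-reference POCS)
#' @param tol relative image-change stopping tolerance (default 1e-6)
#' @param phase_ref optional fixed phase array (radians) on the image grid;
#'   when `NULL` the adaptive smoothed-phase estimate is used
#' @param phase_sigma smoothing width (voxels) of the adaptive phase
#'   estimate (default 3)
#' @return complex image array
#' @export
pocs_reconstruct <- function(k_partial, n_iter = 50L, tol = 1e-6,
                             phase_ref = NULL, phase_sigma = 3) {
  stopifnot(inherits(k_partial, "kspace"))
  params <- k_partial$params
  pe <- params$pe_axis
  amask <- k_partial$acquired_mask
  n_pe <- length(amask)
  ctr <- dc_index(n_pe)
  if (!amask[ctr]) stop("POCS needs the acquired center row")
  rows <- which(amask)
  m <- max(ctr - min(rows), max(rows) - ctr)
  if (m < 1L)
    stop("no low-frequency band available (only the center row acquired)")
  if (!is.null(phase_ref))
    stopifnot(identical(dim(phase_ref), dim(k_partial$data)))

  x <- ifftc(k_partial$data)
  for (it in seq_len(n_iter)) {
    ph <- if (is.null(phase_ref)) smoothed_phase(x, phase_sigma) else phase_ref
    y <- Re(x * exp(-1i * ph)) * exp(1i * ph)
    kk <- fftc(y)
    kk <- zero_unacquired(kk, !amask, pe)   # keep only the synthesised part
    kk <- kk + k_partial$data               # restore acquired samples exactly
    x_new <- ifftc(kk)
    delta <- sqrt(sum(Mod(x_new - x)^2) / max(sum(Mod(x)^2), .Machine$double.eps))
    x <- x_new
    if (delta < tol) break
  }
  x
}
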