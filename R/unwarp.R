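# Distortion correction: opposite-direction unwarping of the blip-up and
# blip-down half-images, combined either by complex averaging or by
# least-squares restoration (solving the joint resampling system of the
# two oppositely distorted observations per PE column).

#' Unwarp a distorted image with a field map
#'
#' Inverse of the [distort_image()] model: each output voxel is resampled
#' from PE position `y + polarity * d(y)` (linear interpolation, applied to
#' real and imaginary parts independently for complex input), with optional
#' division by the Jacobian intensity factor.
#'
#' @param img real or complex image array
#' @param field a [field_map()] in Hz
#' @param polarity `+1` or `-1`, matching the distortion being undone
#' @param params an [acq_params()]
#' @param jacobian divide by the local compression factor (default TRUE)
#' @return unwarped image, same shape and mode as `img`
#' @export
apply_field <- function(img, field, polarity, params, jacobian = TRUE) {
  stopifnot(polarity %in% c(-1, 1))
  d <- field_displacement(field, params)
  out <- pe_resample(img, polarity * d, params$pe_axis, "linear")
  if (jacobian) {
    jac <- pmax(1 - polarity * pe_gradient(d, params$pe_axis), 0.2)
    out <- out / jac
  }
  out
}

# Dense N x N matrix resampling a column at positions y + shift (linear
# interpolation, zero outside), rows optionally scaled by `rowscale`.
resample_matrix <- function(shift, rowscale = NULL) {
  n <- length(shift)
  pos <- seq_len(n) + shift
  j0 <- floor(pos)
  w <- pos - j0
  A <- matrix(0, n, n)
  put <- function(j, wt) {
    ok <- j >= 1 & j <= n & wt != 0
    if (any(ok)) A[cbind(which(ok), j[ok])] <<- A[cbind(which(ok), j[ok])] + wt[ok]
  }
  put(as.integer(j0), 1 - w)
  put(as.integer(j0) + 1L, w)
  if (!is.null(rowscale)) A <- A * rowscale
  A
}

# Regularized joint solve for one PE column.
lsr_column <- function(iu, id, d, jacobian) {
  n <- length(d)
  dd <- c(if (n >= 2) d[2] - d[1] else 0,
          if (n >= 3) (d[3:n] - d[1:(n - 2)]) / 2,
          if (n >= 2) d[n] - d[n - 1])
  ju <- if (jacobian) pmax(1 - dd, 0.05) else NULL
  jd <- if (jacobian) pmax(1 + dd, 0.05) else NULL
  Au <- resample_matrix(-d, ju)
  Ad <- resample_matrix(d, jd)
  G <- crossprod(Au) + crossprod(Ad)
  dg <- diag(G)
  dmax <- max(dg, .Machine$double.eps)
  eps <- 1e-10 * dmax + ifelse(dg < 1e-3 * dmax, 1e-3 * dmax, 0)
  diag(G) <- dg + eps
  rhs <- crossprod(Au, cbind(Re(iu), Im(iu))) +
    crossprod(Ad, cbind(Re(id), Im(id)))
  sol <- solve(G, rhs)
  complex(real = sol[, 1], imaginary = sol[, 2])
}

#' Least-squares restoration from an oppositely distorted pair
#'
#' Per PE column, builds the two linear interpolation operators mapping an
#' undistorted column to the observed blip-up and blip-down columns
#' (including Jacobian intensity modulation) and returns the solution of
#' the joint regularized least-squares system.  A small Tikhonov term is
#' added only where the normal matrix lacks support (voxels mapped from
#' outside the field of view), so well-posed columns are solved
#' essentially unregularized — with a zero field the result is exactly the
#' average of the two inputs.
#'
#' @param img_up,img_down distorted observations (real or complex) on the
#'   same grid
#' @param field a [field_map()] in Hz
#' @param params an [acq_params()]
#' @param jacobian include Jacobian modulation in the operators
#'   (default TRUE)
#' @return restored image, complex if either input is complex
#' @export
lsr_restore <- function(img_up, img_down, field, params, jacobian = TRUE) {
  stopifnot(identical(dim(img_up), dim(img_down)))
  d <- field_displacement(field, params)
  if (!all(is.finite(d))) stop("field must be finite")
  was_complex <- is.complex(img_up) || is.complex(img_down)
  iu <- as_vol(img_up + 0i); id <- as_vol(img_down + 0i)
  dv <- as_vol(array(d, dim(as_vol(img_up + 0i))))
  pe <- params$pe_axis
  p <- perm_pe_second(pe)
  iu <- aperm(iu, p); id <- aperm(id, p); dv <- aperm(dv, p)
  out <- iu * 0
  for (z in seq_len(dim(iu)[3])) {
    for (i in seq_len(dim(iu)[1])) {
      out[i, , z] <- lsr_column(iu[i, , z], id[i, , z], dv[i, , z], jacobian)
    }
  }
  out <- aperm(out, order(p))
  out <- restore_dim(out, as_vol(img_up))
  dim(out) <- if (is.null(dim(img_up))) NULL else dim(img_up)
  if (!was_complex) out <- Re(out)
  out
}

# Centered 1D DFT matrix of size n (DC at floor(n/2), matching fftc).
dft1c_matrix <- function(n) {
  W <- matrix(0 + 0i, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- 1
    W[, j] <- as.vector(fftshift(stats::fft(ifftshift(e))))
  }
  W
}

# Masked-operator LSR for the correction split: per PE column solves
#   min || M_up F A+ o - k_up ||^2 + || M_dn F A- o - k_dn ||^2 + eps||o||^2
# i.e. the forward model of each zero-filled half image includes its
# PE-row mask, so the pair jointly determines the undistorted column on
# all acquired rows (a zero field reduces to the partial-Fourier-limited
# reconstruction exactly, up to the support guard).
lsr_restore_halves <- function(halves, field, params, jacobian = TRUE) {
  d <- field_displacement(field, params)
  pe <- params$pe_axis
  iu <- as_vol(ifftc(halves$k_up$data))
  id <- as_vol(ifftc(halves$k_down$data))
  dv <- as_vol(array(d, dim(iu)))
  p <- perm_pe_second(pe)
  iu <- aperm(iu, p); id <- aperm(id, p); dv <- aperm(dv, p)
  n <- dim(iu)[2]
  W <- dft1c_matrix(n)
  Winv <- Conj(t(W)) / n
  Cu <- Winv %*% (halves$k_up$acquired_mask * W)
  Cd <- Winv %*% (halves$k_down$acquired_mask * W)
  out <- iu * 0
  for (z in seq_len(dim(iu)[3])) {
    for (i in seq_len(dim(iu)[1])) {
      dcol <- dv[i, , z]
      dd <- pe_gradient(matrix(dcol, 1), 2L)[1, ]
      Bu <- Cu %*% resample_matrix(-dcol, if (jacobian) pmax(1 - dd, 0.05))
      Bd <- Cd %*% resample_matrix(dcol, if (jacobian) pmax(1 + dd, 0.05))
      G <- Conj(t(Bu)) %*% Bu + Conj(t(Bd)) %*% Bd
      dg <- Re(diag(G))
      dmax <- max(dg, .Machine$double.eps)
      eps <- 1e-10 * dmax + ifelse(dg < 1e-3 * dmax, 1e-3 * dmax, 0)
      diag(G) <- diag(G) + eps
      rhs <- Conj(t(Bu)) %*% iu[i, , z] + Conj(t(Bd)) %*% id[i, , z]
      out[i, , z] <- solve(G, rhs)
    }
  }
  out <- aperm(out, order(p))
  dim(out) <- params$matrix_shape
  out
}

#' Correct a centric EPI k-space with an estimated field map
#'
#' Splits the k-space with the correction convention (centre line only in
#' the blip-up half, all other missing samples zero-filled — no POCS at
#' this stage), inverse-transforms both halves to complex images, and
#' combines them either by least-squares restoration — solving the joint
#' per-column system whose forward model includes both the opposite
#' distortions and each half's PE-row mask — or by complex averaging of
#' the two opposite-direction unwarping results (each half scaled by 2,
#' since it carries about half of the object's PE spectrum).  With a zero
#' field either combination reduces to the partial-Fourier-limited
#' reconstruction of the source k-space.
#'
#' @param k a centric [kspace()]
#' @param field a [field_map()] in Hz
#' @param use_lsr combine by least-squares restoration (default TRUE);
#'   otherwise complex averaging
#' @return list with `complex` and `magnitude` image arrays
#' @export
correct_cenepi <- function(k, field, use_lsr = TRUE) {
  stopifnot(inherits(k, "kspace"))
  params <- k$params
  halves <- split_for_correction(k)
  out <- if (use_lsr) {
    lsr_restore_halves(halves, field, params)
  } else {
    (apply_field(2 * ifftc(halves$k_up$data), field, +1, params) +
       apply_field(2 * ifftc(halves$k_down$data), field, -1, params)) / 2
  }
  list(complex = out, magnitude = Mod(out))
}
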