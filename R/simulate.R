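# Synthetic EPI study generator.  Everything downstream of this file is
# testable offline: a brain-like digital phantom, a smooth B0 field,
# blip-polarity-dependent geometric distortion, centric k-space assembly
# with partial Fourier, a double-echo gradient-echo pair, and a toy
# label/control perfusion series.

# Evaluate code with a local, restorable RNG seed so simulators are
# bitwise reproducible without clobbering the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Normalised in-plane coordinates in [-1, 1] for a slice grid.
norm_coords <- function(n1, n2) {
  x <- (seq_len(n1) - (n1 + 1) / 2) / (n1 / 2)
  y <- (seq_len(n2) - (n2 + 1) / 2) / (n2 / 2)
  list(x = matrix(x, n1, n2), y = matrix(rep(y, each = n1), n1, n2))
}

#' Generate a brain-like complex digital phantom
#'
#' A compact bright object built from a few overlapping ellipses around the
#' field-of-view centre, with darker internal structures, smooth
#' multiplicative texture, and a smooth low-order phase.  The background is
#' exactly zero and the object is confined so that the outer ~30% of the
#' field of view stays empty.
#'
#' @param shape integer vector (2 or 3 axes); in-plane axes must be >= 32
#' @param seed integer seed; the output is bitwise reproducible
#' @return complex array of dimension `shape`
#' @export
make_phantom <- function(shape, seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 8L)) stop("degenerate shape: every axis needs >= 8 voxels")
  if (any(shape[1:2] < 32L)) stop("in-plane axes must be >= 32 voxels")
  n3 <- if (length(shape) == 3L) shape[3] else 1L
  with_local_seed(seed, {
    co <- norm_coords(shape[1], shape[2])
    vol <- array(0, c(shape[1], shape[2], n3))
    phs <- array(0, c(shape[1], shape[2], n3))
    # slice profile: slightly smaller brain toward the outer partitions
    zprof <- if (n3 > 1L) {
      zz <- (seq_len(n3) - (n3 + 1) / 2) / (n3 / 2)
      sqrt(pmax(1 - 0.35 * zz^2, 0.5))
    } else 1
    n_ell <- sample(3:5, 1L)
    ecx <- stats::runif(n_ell, -0.08, 0.08)
    ecy <- stats::runif(n_ell, -0.08, 0.08)
    era <- stats::runif(n_ell, 0.35, 0.55)
    erb <- stats::runif(n_ell, 0.35, 0.55)
    eth <- stats::runif(n_ell, 0, pi)
    n_int <- 3L
    icx <- stats::runif(n_int, -0.25, 0.25)
    icy <- stats::runif(n_int, -0.25, 0.25)
    ira <- stats::runif(n_int, 0.06, 0.15)
    irb <- stats::runif(n_int, 0.06, 0.15)
    ilv <- stats::runif(n_int, 0.45, 0.75)
    # low-order phase, |phi| kept well under pi
    pc <- stats::runif(6, -0.15, 0.15)
    tex <- gaussian_smooth(array(stats::rnorm(prod(c(shape[1:2], n3))),
                                 c(shape[1], shape[2], n3)), 2)
    tex <- tex / max(abs(tex))
    inside_ell <- function(cx, cy, ra, rb, th, s) {
      dx <- co$x - cx; dy <- co$y - cy
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      (u / (ra * s))^2 + (v / (rb * s))^2 <= 1
    }
    for (z in seq_len(n3)) {
      s <- if (length(zprof) > 1L) zprof[z] else zprof
      obj <- matrix(FALSE, shape[1], shape[2])
      for (e in seq_len(n_ell))
        obj <- obj | inside_ell(ecx[e], ecy[e], era[e], erb[e], eth[e],
                                s * 0.62)
      sl <- ifelse(obj, 1, 0) * (1 + 0.25 * tex[, , z])
      for (e in seq_len(n_int)) {
        int_e <- inside_ell(icx[e], icy[e], ira[e], irb[e], 0, s)
        sl[obj & int_e] <- sl[obj & int_e] * ilv[e]
      }
      vol[, , z] <- sl
      phs[, , z] <- (pc[1] + pc[2] * co$x + pc[3] * co$y +
                       pc[4] * co$x^2 + pc[5] * co$x * co$y +
                       pc[6] * co$y^2) * obj
    }
    out <- vol * exp(1i * phs)
    dim(out) <- shape
    out
  })
}

#' Generate a smooth synthetic B0 field map
#'
#' Sum of a few random Gaussian bumps, rescaled so the largest absolute
#' off-resonance equals `amplitude_hz`.  Bump widths are at least
#' `smoothness` voxels, which bounds the per-voxel finite-difference
#' gradient by about `amplitude_hz / smoothness`.
#'
#' @param shape integer vector (2 or 3 axes)
#' @param amplitude_hz peak |off-resonance| in Hz (>= 0)
#' @param smoothness minimum bump width in voxels (default 16)
#' @param seed integer seed
#' @return a [field_map()] with provenance `"truth"`
#' @export
make_field_map <- function(shape, amplitude_hz = 40, smoothness = 16,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (amplitude_hz < 0) stop("amplitude_hz must be >= 0")
  n3 <- if (length(shape) == 3L) shape[3] else 1L
  f <- with_local_seed(seed, {
    if (amplitude_hz == 0) {
      array(0, shape)
    } else {
      n_bump <- sample(3:5, 1L)
      acc <- array(0, c(shape[1], shape[2], n3))
      i1 <- array(seq_len(shape[1]), dim(acc))
      i2 <- array(rep(seq_len(shape[2]), each = shape[1]), dim(acc))
      i3 <- array(rep(seq_len(n3), each = shape[1] * shape[2]), dim(acc))
      for (b in seq_len(n_bump)) {
        c1 <- stats::runif(1, 0.2, 0.8) * shape[1]
        c2 <- stats::runif(1, 0.2, 0.8) * shape[2]
        c3 <- stats::runif(1, 0.2, 0.8) * n3
        s12 <- stats::runif(1, smoothness, 2 * smoothness)
        s3 <- max(2, n3 / 2)
        a <- stats::runif(1, -1, 1)
        acc <- acc + a * exp(-((i1 - c1)^2 + (i2 - c2)^2) / (2 * s12^2) -
                               (i3 - c3)^2 / (2 * s3^2))
      }
      acc * (amplitude_hz / max(abs(acc)))
    }
  })
  dim(f) <- shape
  field_map(f, provenance = "truth")
}

#' Apply blip-polarity-dependent geometric distortion
#'
#' Models the EPI susceptibility distortion: each output voxel is resampled
#' from PE position `y - polarity * d(y)` where
#' `d = field * total_readout_time` (voxels), with linear interpolation and
#' zero outside the field of view.  With `modulate_jacobian = TRUE` the
#' intensity is scaled by the compression/stretch of the warp so the
#' integrated signal along each PE line is conserved.
#'
#' @param img real or complex image array
#' @param field a [field_map()] (Hz) on the same grid
#' @param polarity `+1` (blip-up) or `-1` (blip-down)
#' @param params an [acq_params()]
#' @param modulate_jacobian logical; apply intensity modulation (default TRUE)
#' @return distorted image, same shape as `img`
#' @export
distort_image <- function(img, field, polarity, params,
                          modulate_jacobian = TRUE) {
  stopifnot(polarity %in% c(-1, 1))
  d <- field_displacement(field, params)
  if (!identical(dim(as_vol(img)), dim(as_vol(d))))
    stop("image and field grids do not match")
  out <- pe_resample(img, -polarity * d, params$pe_axis, "linear")
  if (modulate_jacobian) {
    jac <- 1 - polarity * pe_gradient(d, params$pe_axis)
    out <- out * pmax(jac, 0.05)
  }
  out
}

#' Assemble a single centric EPI k-space from a distorted pair
#'
#' Emulates the pseudo-centric trajectory in which the two k-space halves
#' carry opposite blip polarities: PE rows at and above the DC row come
#' from the Fourier transform of the blip-up distorted image, rows below DC
#' (down to the partial-Fourier limit) from the blip-down transform, and
#' rows outside the acquired extent are zero and flagged in the mask.
#'
#' The object's own smooth phase breaks exact Hermitian symmetry, so the
#' partial-Fourier halves are genuinely incomplete and the blip-down
#' quarter keeps the characteristic signal suppression of centric EPI
#' halves.  Field-induced echo-time phase (`2*pi*field*TE`) is not
#' modelled; see the package vignette for what this limitation means.
#'
#' @param img complex phantom image
#' @param field a [field_map()] in Hz
#' @param params an [acq_params()] with a centric trajectory
#' @param noise_sd standard deviation of optional complex Gaussian k-space
#'   noise per real/imaginary channel, relative to the DC magnitude
#'   (default 0 = noiseless)
#' @param seed seed for the noise draw (ignored when `noise_sd = 0`)
#' @return a [kspace()] object
#' @export
simulate_cenepi_kspace <- function(img, field, params, noise_sd = 0,
                                   seed = 1L) {
  if (!is_centric(params)) stop("params$trajectory must be centric")
  if (!identical(as.integer(dim(img)), params$matrix_shape))
    stop("image shape does not match params$matrix_shape")
  ku <- fftc(distort_image(img + 0i, field, +1, params))
  kd <- fftc(distort_image(img + 0i, field, -1, params))
  n_pe <- params$matrix_shape[params$pe_axis]
  ctr <- dc_index(n_pe)
  mask <- pf_acquired_mask(params)
  data <- kd
  up_rows <- ctr:n_pe
  data <- pe_slab_assign(data, params$pe_axis, up_rows,
                         pe_slab(ku, params$pe_axis, up_rows))
  data <- zero_unacquired(data, mask, params$pe_axis)
  if (noise_sd > 0) {
    scale <- noise_sd * max(Mod(data))
    noise <- with_local_seed(seed, {
      array(complex(real = stats::rnorm(length(data)),
                    imaginary = stats::rnorm(length(data))) * scale,
            dim(data))
    })
    data <- zero_unacquired(data + noise, mask, params$pe_axis)
  }
  kspace(data, mask, params)
}

#' Simulate a distortion-free double-echo GRE pair
#'
#' Two complex gradient-echo images with identical magnitude and a phase
#' difference of `2*pi*field*(te2 - te1)`; no geometric distortion (the GRE
#' readout bandwidth is high enough that off-resonance shifts are
#' negligible).
#'
#' @param img complex or magnitude image (its phase is kept as the TE1 phase
#'   offset)
#' @param field a [field_map()] in Hz
#' @param te1_s,te2_s echo times in seconds, `te2_s > te1_s`
#' @return list with complex arrays `echo1` and `echo2`
#' @export
simulate_gre_pair <- function(img, field, te1_s = 4.92e-3, te2_s = 7.38e-3) {
  if (te2_s <= te1_s) stop("te2_s must exceed te1_s")
  f <- if (inherits(field, "field_map")) field$values else field
  mag <- Mod(img)
  ph0 <- Arg(img + 0i)
  list(echo1 = mag * exp(1i * (ph0 + 2 * pi * f * te1_s)),
       echo2 = mag * exp(1i * (ph0 + 2 * pi * f * te2_s)))
}

#' Simulate a toy label/control perfusion series
#'
#' Control volumes are the phantom magnitude plus Gaussian noise; label
#' volumes lose `perfusion_fraction` of the signal inside the gray-matter
#' mask; M0 volumes are noisy copies of the control.  The background mask
#' is everything outside the (dilated) object support.
#'
#' @param img phantom image (magnitude is used)
#' @param gm_mask logical gray-matter mask (nonempty)
#' @param perfusion_fraction fractional label/control signal difference in
#'   gray matter, in (0, 1); default 0.008, which puts gray-matter CBF near
#'   the textbook ~70 ml/100 g/min under the default quantification constants
#' @param noise_sd Gaussian noise SD in image units (default 0.01)
#' @param n_pairs number of label/control pairs (default 34)
#' @param n_m0 number of M0 volumes (default 15)
#' @param seed integer seed
#' @return an object of class `"perfusion_series"`: 4D arrays `control`,
#'   `label`, `m0` plus `gm_mask` and `bg_mask`
#' @export
simulate_perfusion_series <- function(img, gm_mask, perfusion_fraction = 0.008,
                                      noise_sd = 0.01, n_pairs = 34L,
                                      n_m0 = 15L, seed = 1L) {
  if (!(perfusion_fraction >= 0 && perfusion_fraction < 1))
    stop("perfusion_fraction must lie in [0, 1)")
  if (!any(gm_mask)) stop("gm_mask is empty")
  mag <- as_vol(Mod(img))
  gm <- as_vol(gm_mask)
  stopifnot(identical(dim(gm), dim(mag)))
  support <- mag > 0
  bg <- !as.logical(dilate_mask(support, radius = 2L))
  dim(bg) <- dim(mag)
  d4 <- function(n) c(dim(mag), n)
  with_local_seed(seed, {
    noise <- function(n) array(stats::rnorm(prod(d4(n)), sd = noise_sd), d4(n))
    control <- array(mag, d4(n_pairs)) + noise(n_pairs)
    label <- array(mag - perfusion_fraction * mag * gm, d4(n_pairs)) +
      noise(n_pairs)
    m0 <- array(mag, d4(n_m0)) + noise(n_m0)
    structure(list(control = control, label = label, m0 = m0,
                   gm_mask = gm & !bg, bg_mask = bg & !gm),
              class = "perfusion_series")
  })
}
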