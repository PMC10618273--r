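# File interfaces: NIfTI-1 for images, masks and field maps (complex data
# as a real/imaginary pair), a YAML sidecar for acquisition metadata, and
# a plain-text PE-direction sidecar mirroring the usual acquisition-
# parameter text convention (direction sign + total readout time).

#' Write / read an image volume as NIfTI-1
#'
#' Complex arrays are stored as a `<stem>_real.nii.gz` /
#' `<stem>_imag.nii.gz` pair; real arrays (and logical masks, stored as
#' 0/1) as `<stem>.nii.gz`.
#'
#' @param img array to write
#' @param stem output path without extension
#' @return (write) invisible vector of paths; (read) the array
#' @export
image_write <- function(img, stem) {
  if (is.complex(img)) {
    p <- c(paste0(stem, "_real.nii.gz"), paste0(stem, "_imag.nii.gz"))
    RNifti::writeNifti(Re(img), p[1])
    RNifti::writeNifti(Im(img), p[2])
  } else {
    p <- paste0(stem, ".nii.gz")
    RNifti::writeNifti(img * 1, p)
  }
  invisible(p)
}

nifti_array <- function(path) {
  x <- RNifti::readNifti(path)
  array(as.vector(x), dim = dim(x))
}

#' @rdname image_write
#' @export
image_read <- function(stem) {
  re_p <- paste0(stem, "_real.nii.gz")
  if (file.exists(re_p)) {
    re <- nifti_array(re_p)
    im <- nifti_array(paste0(stem, "_imag.nii.gz"))
    re + 1i * im
  } else {
    nifti_array(paste0(stem, ".nii.gz"))
  }
}

acq_params_to_list <- function(params) {
  list(matrix_shape = as.integer(params$matrix_shape),
       pe_axis = params$pe_axis,
       partial_fourier = params$partial_fourier,
       total_readout_time = params$total_readout_time,
       trajectory = params$trajectory,
       lines_per_jump = params$lines_per_jump)
}

acq_params_from_list <- function(x) {
  acq_params(matrix_shape = unlist(x$matrix_shape),
             pe_axis = x$pe_axis,
             partial_fourier = x$partial_fourier,
             total_readout_time = x$total_readout_time,
             trajectory = x$trajectory,
             lines_per_jump = x$lines_per_jump)
}

#' Write / read a k-space container
#'
#' Stores the complex data as a real/imaginary NIfTI pair plus a YAML
#' sidecar (`<stem>.yaml`) holding the acquisition parameters and the
#' acquired-line mask.  `kspace_read(kspace_write(k))` round-trips exactly.
#'
#' @param k a [kspace()]
#' @param stem output path without extension
#' @return (write) invisible stem; (read) a [kspace()]
#' @export
kspace_write <- function(k, stem) {
  stopifnot(inherits(k, "kspace"))
  image_write(k$data, stem)
  yaml::write_yaml(c(acq_params_to_list(k$params),
                     list(acquired_mask = as.integer(k$acquired_mask))),
                   paste0(stem, ".yaml"))
  invisible(stem)
}

#' @rdname kspace_write
#' @export
kspace_read <- function(stem) {
  meta <- yaml::read_yaml(paste0(stem, ".yaml"))
  params <- acq_params_from_list(meta)
  data <- image_read(stem)
  dim(data) <- params$matrix_shape
  kspace(data, as.logical(unlist(meta$acquired_mask)), params)
}

#' Write a field map as NIfTI with a PE-direction sidecar
#'
#' Writes the off-resonance in Hz (`<stem>_hz.nii.gz`), the displacement
#' map in voxels (`<stem>_voxels.nii.gz`), and a one-line text sidecar
#' giving the PE direction vector and total readout time.
#'
#' @param field a [field_map()]
#' @param params an [acq_params()]
#' @param stem output path without extension
#' @return invisible stem
#' @export
fieldmap_write <- function(field, params, stem) {
  stopifnot(inherits(field, "field_map"))
  RNifti::writeNifti(field$values, paste0(stem, "_hz.nii.gz"))
  RNifti::writeNifti(field$values * params$total_readout_time,
                     paste0(stem, "_voxels.nii.gz"))
  dir_vec <- rep(0L, length(params$matrix_shape))
  dir_vec[params$pe_axis] <- 1L
  writeLines(paste(c(dir_vec, format(params$total_readout_time)),
                   collapse = " "),
             paste0(stem, "_pedir.txt"))
  invisible(stem)
}
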