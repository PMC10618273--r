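#' Acquisition parameters for a centric EPI k-space
#'
#' Bundles the geometry and timing metadata every stage of the pipeline
#' needs: the matrix size, which axis is phase-encoded, the partial-Fourier
#' fraction, and the total readout time that converts off-resonance (Hz)
#' into voxel displacement along the phase-encode (PE) axis.
#'
#' Axis convention: axis 1 = readout, axis 2 = phase encode, axis 3 =
#' partition/slice; a blip-up acquisition shifts signal toward +PE.
#'
#' @param matrix_shape integer vector of voxels per axis (2 or 3 axes)
#' @param pe_axis index of the phase-encode axis (default 2)
#' @param partial_fourier acquired fraction of the full PE extent, in (0.5, 1]
#' @param total_readout_time seconds between the first and last PE sample;
#'   displacement (voxels) = field (Hz) x `total_readout_time`
#' @param trajectory one of `"centric_1shot"`, `"centric_2shot"`,
#'   `"linear_up"`, `"linear_down"`
#' @param lines_per_jump number of PE lines between jump blips in the
#'   centric trajectory (metadata only; jump-blip eddy currents are not
#'   modelled)
#' @return an object of class `"acq_params"`
#' @export
acq_params <- function(matrix_shape,
                       pe_axis = 2L,
                       partial_fourier = 0.75,
                       total_readout_time = 0.032,
                       trajectory = c("centric_1shot", "centric_2shot",
                                      "linear_up", "linear_down"),
                       lines_per_jump = 4L) {
  trajectory <- match.arg(trajectory)
  matrix_shape <- as.integer(matrix_shape)
  stopifnot(length(matrix_shape) %in% c(2L, 3L), all(matrix_shape >= 1L))
  pe_axis <- as.integer(pe_axis)
  if (pe_axis < 1L || pe_axis > length(matrix_shape))
    stop("pe_axis must index an axis of matrix_shape")
  if (!(partial_fourier > 0.5 && partial_fourier <= 1))
    stop("partial_fourier must lie in (0.5, 1]")
  if (total_readout_time <= 0) stop("total_readout_time must be positive")
  structure(list(matrix_shape = matrix_shape,
                 pe_axis = pe_axis,
                 partial_fourier = partial_fourier,
                 total_readout_time = total_readout_time,
                 trajectory = trajectory,
                 lines_per_jump = as.integer(lines_per_jump)),
            class = "acq_params")
}

is_centric <- function(params)
  params$trajectory %in% c("centric_1shot", "centric_2shot")

#' @export
print.acq_params <- function(x, ...) {
  cat("EPI acquisition parameters\n")
  cat("  matrix:", paste(x$matrix_shape, collapse = " x "),
      " (PE axis", x$pe_axis, ")\n")
  cat("  trajectory:", x$trajectory,
      " partial Fourier:", x$partial_fourier, "\n")
  cat("  total readout time:", x$total_readout_time, "s",
      " (1 Hz =", format(x$total_readout_time, digits = 3), "voxels)\n")
  invisible(x)
}

#' B0 off-resonance field map
#'
#' A per-voxel off-resonance map in Hz on the image grid.  Multiplying by
#' the total readout time gives the PE-axis displacement in voxels.
#'
#' @param values numeric array of off-resonance values (Hz); must be finite
#' @param provenance one of `"truth"`, `"gre"`, `"topup"`, `"split_kspace"`
#' @return an object of class `"field_map"`
#' @export
field_map <- function(values, provenance = c("truth", "gre", "topup",
                                             "split_kspace")) {
  provenance <- match.arg(provenance)
  if (!all(is.finite(values))) stop("field map values must be finite")
  structure(list(values = values, provenance = provenance),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat("B0 field map (", x$provenance, "): ",
      paste(dim(x$values), collapse = " x "),
      ", range [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "] Hz\n", sep = "")
  invisible(x)
}

# Field map (or bare array, interpreted as Hz) -> displacement in voxels.
field_displacement <- function(field, params) {
  v <- if (inherits(field, "field_map")) field$values else field
  d <- v * params$total_readout_time
  if (any(abs(d) >= params$matrix_shape[params$pe_axis]))
    stop("field/readout-time imply displacements exceeding the matrix extent")
  d
}

#' Single-shot centric k-space container
#'
#' Holds a complex k-space array with DC centred at index `floor(N/2)` on
#' every axis, a logical mask of which PE lines were actually acquired, and
#' the acquisition parameters.  Data are zero wherever the mask is false,
#' and the mask depends only on the PE index.
#'
#' @param data complex array with `dim(data) == params$matrix_shape`
#' @param acquired_mask logical vector of length `N_pe` (`TRUE` = acquired);
#'   defaults to the partial-Fourier pattern implied by `params`
#' @param params an [acq_params()] object
#' @return an object of class `"kspace"`
#' @export
kspace <- function(data, acquired_mask = NULL, params) {
  stopifnot(inherits(params, "acq_params"))
  if (!identical(as.integer(dim(data)), params$matrix_shape))
    stop("k-space data shape does not match params$matrix_shape")
  n_pe <- params$matrix_shape[params$pe_axis]
  if (is.null(acquired_mask)) acquired_mask <- pf_acquired_mask(params)
  stopifnot(is.logical(acquired_mask), length(acquired_mask) == n_pe)
  data <- zero_unacquired(as.array(data) + 0i, acquired_mask, params$pe_axis)
  structure(list(data = data, acquired_mask = acquired_mask, params = params),
            class = "kspace")
}

# Partial-Fourier acquisition pattern: the pf*N highest PE indices
# (the lowest (1-pf)*N rows, farthest below DC, are skipped).
pf_acquired_mask <- function(params) {
  n_pe <- params$matrix_shape[params$pe_axis]
  n_acq <- round(params$partial_fourier * n_pe)
  mask <- rep(FALSE, n_pe)
  mask[(n_pe - n_acq + 1L):n_pe] <- TRUE
  mask
}

# Zero all samples on unacquired PE lines.
zero_unacquired <- function(data, acquired_mask, pe_axis) {
  idx <- lapply(dim(data), seq_len)
  idx[[pe_axis]] <- which(!acquired_mask)
  if (length(idx[[pe_axis]]) > 0L) {
    arg <- c(list(data), idx, list(value = 0 + 0i))
    data <- do.call(`[<-`, arg)
  }
  data
}

# Extract / replace a set of PE lines of an array.
pe_slab <- function(data, pe_axis, rows) {
  idx <- lapply(dim(data), seq_len)
  idx[[pe_axis]] <- rows
  do.call(`[`, c(list(data), idx, list(drop = FALSE)))
}

pe_slab_assign <- function(data, pe_axis, rows, value) {
  idx <- lapply(dim(data), seq_len)
  idx[[pe_axis]] <- rows
  do.call(`[<-`, c(list(data), idx, list(value = value)))
}

#' @export
print.kspace <- function(x, ...) {
  cat("k-space: ", paste(dim(x$data), collapse = " x "),
      " (", x$params$trajectory, "), ",
      sum(x$acquired_mask), "/", length(x$acquired_mask),
      " PE lines acquired\n", sep = "")
  invisible(x)
}
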