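# Centred FFT helpers.  Convention throughout the package: the DC sample of
# k-space sits at 0-based index floor(N/2) on every axis (R index
# floor(N/2) + 1), so "upper half" / "lower half" of the phase-encode axis
# are unambiguous for even and odd matrix sizes alike.

axis_shift <- function(x, shift) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(seq_along(d), function(a) {
    n <- d[a]
    s <- shift[a] %% n
    if (s == 0L) seq_len(n) else c((n - s + 1L):n, seq_len(n - s))
  })
  out <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
  dim(out) <- dim(x)
  out
}

#' Shift the zero-frequency sample to the centre of the array
#'
#' `fftshift()` moves the DC component from index 1 to index
#' `floor(n/2) + 1` on every axis; `ifftshift()` is its exact inverse
#' (the two differ for odd lengths).
#'
#' @param x numeric or complex array
#' @return array of the same shape
#' @keywords internal
fftshift <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  axis_shift(x, floor(d / 2))
}

#' @rdname fftshift
#' @keywords internal
ifftshift <- function(x) {
  d <- dim(x); if (is.null(d)) d <- length(x)
  axis_shift(x, ceiling(d / 2))
}

#' Centred forward and inverse discrete Fourier transforms
#'
#' `fftc()` maps an image to k-space with DC at the centre index;
#' `ifftc()` inverts it, including the 1/N normalisation.
#'
#' @param x array (image for `fftc`, k-space for `ifftc`)
#' @return complex array of the same shape
#' @export
fftc <- function(x) fftshift(stats::fft(ifftshift(x)))

#' @rdname fftc
#' @export
ifftc <- function(x) fftshift(stats::fft(ifftshift(x), inverse = TRUE)) / length(x)

# Index of the DC row on an axis of length n (R, 1-based).
dc_index <- function(n) floor(n / 2) + 1L

# Hermitian mirror of a centred k-space: H[i] = Conj(K[m(i)]) where m is the
# point reflection through DC on every axis.  For even lengths the 0-based
# index 0 (Nyquist) maps to itself.
hermitian_mirror <- function(k) {
  d <- dim(k)
  idx <- lapply(d, function(n) {
    c0 <- dc_index(n) - 1L                      # 0-based DC
    m <- (2L * c0 - (seq_len(n) - 1L)) %% n     # 0-based mirror
    m + 1L
  })
  out <- Conj(do.call(`[`, c(list(k), idx, list(drop = FALSE))))
  dim(out) <- d
  out
}
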