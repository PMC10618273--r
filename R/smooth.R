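# Separable in-plane Gaussian smoothing with replicate (edge-clamp) padding.
# Smoothing is applied within each partition slice: the uniformity
# correction and phantom texture are in-plane constructs.

gaussian_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along rows of a matrix (axis 1), replicate padding.
conv_axis1 <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m * k)
  n <- nrow(m)
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(n, r), , drop = FALSE])
  out <- m * 0
  for (i in seq_along(k)) {
    out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

#' Gaussian smoothing of a 2D/3D array (in-plane, per slice)
#'
#' Separable Gaussian filter with kernel radius `ceiling(3*sigma)` and
#' replicate padding at the edges, applied to axes 1 and 2 of each
#' partition slice independently.
#'
#' @param x real 2D/3D array
#' @param sigma standard deviation in voxels (scalar)
#' @return smoothed array of the same shape
#' @export
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gaussian_kernel1d(sigma)
  orig <- x
  x <- as_vol(x)
  for (z in seq_len(dim(x)[3])) {
    sl <- x[, , z]
    sl <- conv_axis1(sl, k)
    sl <- t(conv_axis1(t(sl), k))
    x[, , z] <- sl
  }
  restore_dim(x, orig)
}
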