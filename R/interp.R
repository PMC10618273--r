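# Resampling along the phase-encode axis.  All geometric operations in the
# package reduce to sampling an array at fractional positions y + shift(y)
# along one axis; linear interpolation for images, nearest neighbour for
# masks, zero (or FALSE) outside the field of view.

# Coerce to a 3D array, remembering the original dim.
as_vol <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 3L) stop("only 2D/3D arrays are supported")
  x
}

restore_dim <- function(x, template) {
  dim(x) <- if (length(dim(template)) == 2L) dim(template)[1:2] else dim(template)
  x
}

# Move axis `ax` to position 2 of a 3D array (and back with inverse = TRUE).
perm_pe_second <- function(ax3) {
  p <- switch(ax3, c(2L, 1L, 3L), c(1L, 2L, 3L), c(1L, 3L, 2L))
  p
}

#' Resample an array along the phase-encode axis
#'
#' Returns `out[y] = x[y + shift[y]]` along the PE axis, with linear
#' (default) or nearest-neighbour interpolation and zero fill outside the
#' array extent.  `shift` is a per-voxel displacement in voxels, either a
#' scalar or an array of the same shape as `x`.
#'
#' @param x real or complex 2D/3D array
#' @param shift per-voxel sampling offset (voxels) along the PE axis
#' @param pe_axis which axis is phase-encoded
#' @param method `"linear"` or `"nearest"`
#' @return array of the same shape and mode as `x`
#' @export
pe_resample <- function(x, shift, pe_axis = 2L,
                        method = c("linear", "nearest")) {
  method <- match.arg(method)
  orig <- x
  x <- as_vol(x)
  if (length(shift) == 1L) {
    shift <- array(shift, dim(x))
  } else {
    shift <- as_vol(shift)
    stopifnot(identical(dim(shift), dim(x)))
  }
  p <- perm_pe_second(if (length(dim(orig)) == 2L && pe_axis > 2L)
    stop("pe_axis out of range") else as.integer(pe_axis))
  x <- aperm(x, p); shift <- aperm(shift, p)
  d <- dim(x); n1 <- d[1]; n2 <- d[2]; n3 <- d[3]

  pos <- array(rep(seq_len(n2), each = n1, times = n3), d) + shift
  gather <- function(j) {
    ok <- j >= 1L & j <= n2
    jc <- pmin(pmax(j, 1L), n2)
    lin <- array(seq_len(n1), d) +
      (jc - 1L) * n1 +
      (array(rep(seq_len(n3) - 1L, each = n1 * n2), d)) * (n1 * n2)
    v <- x[lin]
    v[!ok] <- if (is.complex(x)) 0 + 0i else 0
    array(v, d)
  }
  out <- if (method == "nearest") {
    gather(as.integer(round(pos)))
  } else {
    j0 <- floor(pos)
    w <- pos - j0
    (1 - w) * gather(as.integer(j0)) + w * gather(as.integer(j0) + 1L)
  }
  out <- aperm(out, order(p))
  restore_dim(out, orig)
}

# Finite-difference gradient along the PE axis (central in the interior,
# one-sided at the edges), per voxel, in units of 1/voxel.
pe_gradient <- function(x, pe_axis = 2L) {
  orig <- x
  x <- as_vol(x)
  p <- perm_pe_second(as.integer(pe_axis))
  x <- aperm(x, p)
  n2 <- dim(x)[2]
  g <- x * 0
  if (n2 >= 3L) {
    g[, 2:(n2 - 1L), ] <- (x[, 3:n2, , drop = FALSE] -
                             x[, 1:(n2 - 2L), , drop = FALSE]) / 2
  }
  if (n2 >= 2L) {
    g[, 1L, ] <- x[, 2L, ] - x[, 1L, ]
    g[, n2, ] <- x[, n2, ] - x[, n2 - 1L, ]
  }
  g <- aperm(g, order(p))
  restore_dim(g, orig)
}
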