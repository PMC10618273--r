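# Reversed-polarity field estimation: find the smooth PE displacement
# field d whose opposite warps bring the blip-up and blip-down images into
# agreement,
#
#   E(d) = sum_y ( up(y+d(y))*(1+d') - down(y-d(y))*(1-d') )^2
#          + lambda ||L d||^2
#
# with the (optional) Jacobian intensity factors applied multiplicatively
# to the opposite observation — first-order consistent with the
# signal-conserving distortion model and differentiable without division —
# and L the discrete Laplacian (bending-energy penalty).  Solved per slice
# by multi-resolution Levenberg-Marquardt with a diagonal Gauss-Newton
# approximation of the data term; deterministic, d0 = 0.

#' Options for the reversed-polarity field estimator
#'
#' @param sigma per-level Gaussian image smoothing in (fine) voxels,
#'   coarse to fine
#' @param subsample per-level subsampling factors, coarse to fine
#' @param lambda bending-energy regularization weight (>= 0)
#' @param max_iter maximum Gauss-Newton iterations per level
#' @param tol relative objective-decrease stopping tolerance
#' @param jacobian_modulation include Jacobian intensity factors in the
#'   model warps
#' @param z_smooth_sigma smoothing width (slices) applied to the field
#'   across the partition axis after slice-wise estimation (0 = off)
#' @return an object of class `"topup_options"`
#' @export
topup_options <- function(sigma = c(4, 2, 1), subsample = c(4, 2, 1),
                          lambda = 0.3, max_iter = 40L, tol = 1e-8,
                          jacobian_modulation = TRUE, z_smooth_sigma = 1) {
  stopifnot(length(sigma) == length(subsample), lambda >= 0,
            !is.unsorted(rev(subsample)))
  structure(list(sigma = sigma, subsample = as.integer(subsample),
                 lambda = lambda, max_iter = as.integer(max_iter), tol = tol,
                 jacobian_modulation = jacobian_modulation,
                 z_smooth_sigma = z_smooth_sigma),
            class = "topup_options")
}

# Block-average subsampling of a matrix by integer factor s.
block_subsample <- function(m, s) {
  if (s == 1L) return(m)
  g1 <- ceiling(seq_len(nrow(m)) / s)
  g2 <- ceiling(seq_len(ncol(m)) / s)
  cnt <- outer(tabulate(g1), tabulate(g2))
  t(rowsum(t(rowsum(m, g1)), g2)) / cnt
}

# Linear 1D interpolation used when moving a displacement field between
# pyramid grids; positions map block centres to block centres.
resize_field <- function(d, new_dim, old_sub, new_sub) {
  scale <- old_sub / new_sub
  interp_axis <- function(m, n_new, axis) {
    n_old <- dim(m)[axis]
    pos <- (seq_len(n_new) - 0.5) / scale + 0.5
    pos <- pmin(pmax(pos, 1), n_old)
    j0 <- pmin(floor(pos), n_old - 1L); w <- pos - j0
    if (n_old == 1L) { j0 <- rep(1L, n_new); w <- rep(0, n_new) }
    if (axis == 1L) {
      (1 - w) * m[j0, , drop = FALSE] +
        w * m[pmin(j0 + 1L, n_old), , drop = FALSE]
    } else {
      sweep(m[, j0, drop = FALSE], 2, 1 - w, `*`) +
        sweep(m[, pmin(j0 + 1L, n_old), drop = FALSE], 2, w, `*`)
    }
  }
  d <- interp_axis(d, new_dim[1], 1L)
  d <- interp_axis(d, new_dim[2], 2L)
  d * scale
}

# Sparse 5-point Laplacian (Neumann boundaries) for an n1 x n2 grid.
grid_laplacian <- function(n1, n2) {
  n <- n1 * n2
  idx <- matrix(seq_len(n), n1, n2)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(a, b) {
    ii <<- c(ii, a, a); jj <<- c(jj, a, b); xx <<- c(xx, rep(1, length(a)),
                                                     rep(-1, length(a)))
  }
  if (n1 > 1L) {
    a <- as.vector(idx[-n1, ]); b <- as.vector(idx[-1, ])
    add(a, b); add(b, a)
  }
  if (n2 > 1L) {
    a <- as.vector(idx[, -n2]); b <- as.vector(idx[, -1])
    add(a, b); add(b, a)
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  L
}

# Sample a matrix column-wise along PE (axis 2 here) at j + shift, linear.
sample_pe <- function(m, shift) pe_resample(m, shift, pe_axis = 2L, "linear")

warp_residual <- function(up, down, d, jac_mod) {
  dd <- pe_gradient(d, 2L)
  wp <- sample_pe(up, d)
  wm <- sample_pe(down, -d)
  if (jac_mod) {
    wp <- wp * (1 + dd)
    wm <- wm * (1 - dd)
  }
  list(r = wp - wm,
       g = sample_pe(pe_gradient(up, 2L), d) +
         sample_pe(pe_gradient(down, 2L), -d))
}

# Levenberg-Marquardt on one pyramid level; d in level-pixel units
# (PE = axis 2).  Damping is adapted multiplicatively: a rejected step
# boosts mu, an accepted step relaxes it; the objective never increases.
gn_level <- function(up, down, d, lambda, max_iter, tol, jac_mod) {
  n1 <- nrow(up); n2 <- ncol(up)
  L <- grid_laplacian(n1, n2)
  LtL <- Matrix::crossprod(L)
  energy <- function(d) {
    wr <- warp_residual(up, down, d, jac_mod)
    ld <- as.vector(L %*% as.vector(d))
    list(E = sum(wr$r^2) + lambda * sum(ld^2), wr = wr)
  }
  cur <- energy(d)
  mu <- 1e-2 * mean(cur$wr$g^2) + 1e-12
  stall <- 0L
  for (it in seq_len(max_iter)) {
    g <- as.vector(cur$wr$g)
    r <- as.vector(cur$wr$r)
    rhs <- -(g * r + lambda * as.vector(LtL %*% as.vector(d)))
    accepted <- FALSE
    for (boost in 1:10) {
      A <- Matrix::Diagonal(x = g^2 + mu) + lambda * LtL
      delta <- matrix(as.vector(Matrix::solve(A, rhs)), n1, n2)
      ce <- energy(d + delta)
      if (is.finite(ce$E) && ce$E < cur$E) {
        rel <- (cur$E - ce$E) / max(cur$E, .Machine$double.eps)
        d <- d + delta; cur <- ce; mu <- mu / 3
        accepted <- TRUE
        break
      }
      mu <- mu * 10
    }
    if (!accepted) break
    stall <- if (rel < tol) stall + 1L else 0L
    if (stall >= 4L) break
  }
  d
}

estimate_slice <- function(up, down, opts) {
  nlev <- length(opts$sigma)
  d <- NULL
  prev_sub <- NULL
  for (l in seq_len(nlev)) {
    s <- opts$subsample[l]
    u <- block_subsample(gaussian_smooth(up, opts$sigma[l]), s)
    v <- block_subsample(gaussian_smooth(down, opts$sigma[l]), s)
    d <- if (is.null(d)) u * 0 else resize_field(d, dim(u), prev_sub, s)
    d <- gn_level(u, v, d, opts$lambda, opts$max_iter, opts$tol,
                  opts$jacobian_modulation)
    prev_sub <- s
  }
  if (prev_sub != 1L)
    d <- resize_field(d, dim(up), prev_sub, 1L)
  d
}

#' Estimate a B0 field map from a blip-up / blip-down magnitude pair
#'
#' Finds the smooth displacement field whose opposite warps map the two
#' oppositely distorted images toward a common undistorted space,
#' minimizing the sum-of-squares mismatch plus a bending-energy penalty,
#' by multi-resolution damped Gauss-Newton (Levenberg-Marquardt).
#' Deterministic (the field starts from
#' zero; identical inputs return a null field).  3D volumes are estimated
#' slice-wise along the partition axis, followed by an optional smoothing
#' pass across slices.
#'
#' @param img_up,img_down nonnegative magnitude images on the same grid
#' @param params an [acq_params()]
#' @param opts a [topup_options()]
#' @return a [field_map()] in Hz with provenance `"topup"`
#' @export
estimate_field_topup <- function(img_up, img_down, params,
                                 opts = topup_options()) {
  img_up <- Mod(img_up); img_down <- Mod(img_down)
  if (!all(is.finite(img_up)) || !all(is.finite(img_down)))
    stop("non-finite input image")
  stopifnot(identical(dim(img_up), dim(img_down)))
  # scale each image to unit mean (reversed-polarity distortion conserves
  # the integrated signal, so a genuine pair has equal means; residual
  # global intensity mismatch from preprocessing must not be absorbed
  # into the displacement field via the Jacobian term)
  if (mean(img_up) <= 0 || mean(img_down) <= 0)
    stop("input images are empty")
  up <- as_vol(img_up / mean(img_up))
  down <- as_vol(img_down / mean(img_down))
  pe <- params$pe_axis
  if (pe == 3L) stop("partition axis cannot be the PE axis")
  d <- array(0, dim(up))
  for (z in seq_len(dim(up)[3])) {
    u <- up[, , z]; v <- down[, , z]
    if (pe == 1L) { u <- t(u); v <- t(v) }
    dz <- estimate_slice(u, v, opts)
    d[, , z] <- if (pe == 1L) t(dz) else dz
  }
  if (dim(up)[3] > 1L && opts$z_smooth_sigma > 0) {
    k <- gaussian_kernel1d(opts$z_smooth_sigma)
    d <- aperm(apply(d, c(1, 2), function(v) {
      r <- (length(k) - 1L) %/% 2L
      if (r == 0L) return(v * k)
      pad <- c(rep(v[1], r), v, rep(v[length(v)], r))
      stats::filter(pad, k, sides = 2)[(r + 1L):(r + length(v))]
    }), c(2, 3, 1))
  }
  vals <- d / params$total_readout_time
  dim(vals) <- dim(img_up)
  field_map(vals, provenance = "topup")
}
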