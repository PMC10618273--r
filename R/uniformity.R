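# Uniformity correction: divide an image by a lowpass (bias) estimate whose
# Gaussian smoothing width is either a constant high value (sigma = 8) or
# assigned per voxel from the position between the mask's centre of mass
# (sigma = 0.5) and the brain boundary (sigma = 8).

SIGMA_MIN <- 0.5
SIGMA_MAX <- 8
SIGMA_BANK <- c(0.5, 1, 2, 4, 8)

#' Per-voxel Gaussian smoothing width for uniformity correction
#'
#' In `"constant"` mode the width is 8 voxels everywhere.  In
#' `"location_dependent"` mode each in-mask voxel gets
#' `0.5 + 7.5 * t`, where `t` is its relative radial position between the
#' slice's mask centre of mass (`t = 0`) and the boundary intersection of
#' the ray from the centre of mass through the voxel (`t = 1`, clamped);
#' outside the mask the width is 8.  Rays are marched in-plane with
#' half-voxel steps and nearest-neighbour mask lookups.
#'
#' @param mask logical brain mask (2D/3D; slices are treated independently)
#' @param mode `"constant"` or `"location_dependent"`
#' @return numeric array of smoothing widths (voxels), same shape as `mask`
#' @export
sigma_field <- function(mask, mode = c("constant", "location_dependent")) {
  mode <- match.arg(mode)
  if (!any(mask)) stop("sigma_field needs a nonempty mask")
  out <- array(SIGMA_MAX, dim(mask))
  if (mode == "constant") return(out)
  m3 <- as_vol(mask)
  o3 <- as_vol(out)
  d <- dim(m3)
  for (z in seq_len(d[3])) {
    sl <- m3[, , z]
    if (!any(sl)) next
    idx <- which(sl)
    ii <- (idx - 1L) %% d[1] + 1L
    jj <- (idx - 1L) %/% d[1] + 1L
    com <- c(mean(ii), mean(jj))
    vx <- ii - com[1]; vy <- jj - com[2]
    r <- sqrt(vx^2 + vy^2)
    ux <- ifelse(r > 1e-9, vx / pmax(r, 1e-9), 0)
    uy <- ifelse(r > 1e-9, vy / pmax(r, 1e-9), 0)
    alive <- r > 1e-9
    t_exit <- rep(0.5, length(idx))
    t <- 0.5
    t_max <- 2 * sqrt(d[1]^2 + d[2]^2)
    while (any(alive) && t <= t_max) {
      px <- round(ii + ux * t); py <- round(jj + uy * t)
      inb <- px >= 1 & px <= d[1] & py >= 1 & py <= d[2]
      inside <- rep(FALSE, length(idx))
      inside[inb] <- sl[cbind(px[inb], py[inb])]
      exited <- alive & !inside
      t_exit[exited] <- t
      alive <- alive & inside
      t <- t + 0.5
    }
    b <- r + t_exit - 0.5
    rel <- pmin(pmax(r / pmax(b, 1e-9), 0), 1)
    sig <- SIGMA_MIN + (SIGMA_MAX - SIGMA_MIN) * rel
    osl <- o3[, , z]
    osl[idx] <- sig
    o3[, , z] <- osl
  }
  dim(o3) <- dim(mask)
  o3
}

#' Spatially varying Gaussian lowpass of a max-filled target image
#'
#' Builds the target image — the original inside the mask, the global
#' maximum outside (suppressing background noise in the bias estimate) —
#' and smooths it with a per-voxel width.  The varying-width filter is
#' realised by interpolating linearly in sigma between a bank of
#' constant-width filtered images (sigma in {0.5, 1, 2, 4, 8}); a constant
#' sigma map equal to a bank value therefore reproduces plain Gaussian
#' filtering exactly.
#'
#' @param img magnitude image array
#' @param mask logical object mask (must not be all-background)
#' @param sigma scalar or per-voxel array of smoothing widths (voxels)
#' @return strictly positive smoothed array of the same shape
#' @export
lowpass_image <- function(img, mask, sigma) {
  img <- Mod(img)
  stopifnot(identical(dim(img), dim(mask)))
  if (!any(mask)) stop("all-background mask")
  target <- img
  target[!mask] <- max(img)
  if (length(sigma) == 1L) sigma <- array(sigma, dim(img))
  stopifnot(identical(dim(sigma), dim(img)))
  sigma <- pmin(pmax(sigma, SIGMA_BANK[1]), SIGMA_BANK[length(SIGMA_BANK)])
  bank_vals <- sort(unique(c(SIGMA_BANK,
                             if (length(unique(as.vector(sigma))) == 1L)
                               sigma[1])))
  bank <- lapply(bank_vals, function(s) gaussian_smooth(target, s))
  lo <- findInterval(sigma, bank_vals, rightmost.closed = TRUE)
  lo <- pmin(pmax(lo, 1L), length(bank_vals) - 1L)
  out <- array(0, dim(img))
  for (b in seq_len(length(bank_vals) - 1L)) {
    sel <- lo == b
    if (!any(sel)) next
    w <- (sigma[sel] - bank_vals[b]) / (bank_vals[b + 1L] - bank_vals[b])
    out[sel] <- (1 - w) * bank[[b]][sel] + w * bank[[b + 1L]][sel]
  }
  pmax(out, .Machine$double.eps)
}

#' Uniformity correction by lowpass division
#'
#' Divides the image by its [lowpass_image()] bias estimate.  Used only to
#' equalise the two field-estimation inputs; corrected EPI images never
#' pass through this operation.
#'
#' @inheritParams lowpass_image
#' @return bias-corrected array, finite everywhere
#' @export
uniformity_correct <- function(img, mask, sigma) {
  img <- Mod(img)
  lp <- lowpass_image(img, mask, sigma)
  guard <- 1e-6 * max(lp)
  img / pmax(lp, guard)
}
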