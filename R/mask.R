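# Automatic brain masking: Otsu thresholding with largest-component /
# hole-fill postprocessing, triangular-element dilation, and field-based
# mask warping.  Masks are logical arrays on the image grid.

# Shift a logical/numeric array along one axis with FALSE/0 padding.
shift_axis <- function(x, axis, by) {
  if (by == 0L) return(x)
  d <- dim(x)
  idx <- lapply(d, seq_len)
  src <- seq_len(d[axis]) - by
  ok <- src >= 1L & src <= d[axis]
  out <- array(if (is.logical(x)) FALSE else 0, d)
  if (!any(ok)) return(out)
  idx_dst <- idx; idx_dst[[axis]] <- which(ok)
  idx_src <- idx; idx_src[[axis]] <- src[ok]
  do.call(`[<-`, c(list(out), idx_dst,
                   list(value = do.call(`[`, c(list(x), idx_src,
                                               list(drop = FALSE))))))
}

# One step of 6-connected (4-connected in 2D) frontier growth inside `domain`.
grow_step <- function(frontier, domain) {
  nb <- frontier
  for (a in seq_along(dim(frontier))) {
    if (dim(frontier)[a] == 1L) next
    nb <- nb | shift_axis(frontier, a, 1L) | shift_axis(frontier, a, -1L)
  }
  nb & domain
}

# Connected component of `domain` containing the seed voxels.
flood_fill <- function(domain, seeds) {
  comp <- seeds & domain
  repeat {
    nxt <- grow_step(comp, domain)
    if (sum(nxt) == sum(comp)) return(comp)
    comp <- nxt
  }
}

largest_component <- function(mask) {
  remaining <- mask
  best <- NULL; best_n <- -1L
  while (any(remaining)) {
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1L]] <- TRUE
    comp <- flood_fill(remaining, seed)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  best
}

fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  border <- array(FALSE, d)
  for (a in seq_along(d)) {
    if (d[a] == 1L) next   # singleton axes (e.g. one slice) have no faces
    idx <- lapply(d, seq_len)
    idx[[a]] <- c(1L, d[a])
    border <- do.call(`[<-`, c(list(border), idx, list(value = TRUE)))
  }
  outside <- flood_fill(bg, bg & border)
  mask | (bg & !outside)
}

# Otsu threshold over a 256-bin histogram: the cut maximizing the
# between-class variance w0*w1*(mu0-mu1)^2, returned as an intensity value.
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (rng[1] == rng[2]) stop("degenerate histogram: image is constant")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(h)
  w1 <- sum(h) - w0
  s0 <- cumsum(h * mids)
  mu0 <- s0 / pmax(w0, 1)
  mu1 <- (sum(h * mids) - s0) / pmax(w1, 1)
  crit <- w0 * w1 * (mu0 - mu1)^2
  crit[w0 == 0 | w1 == 0] <- -Inf
  edges[which.max(crit) + 1L]
}

#' Automatic brain mask by Otsu thresholding
#'
#' Thresholds a magnitude image at the 256-bin Otsu cut (the boundary
#' maximizing the between-class intensity variance), keeps the largest
#' connected component, and fills interior holes.
#'
#' @param img magnitude image array (2D/3D) with at least two distinct values
#' @return logical mask of the same shape
#' @export
otsu_mask <- function(img) {
  img <- Mod(img)
  thr <- otsu_threshold(as.vector(img))
  m <- as_vol(img > thr)
  if (!any(m)) stop("Otsu threshold produced an empty mask")
  m <- fill_holes(largest_component(m))
  dim(m) <- dim(img)
  m
}

# Offsets (readout, PE) of a triangular structuring element of the given
# radius: the origin plus rows fanning out along +PE (or both directions).
triangle_offsets <- function(radius, direction = "up") {
  off <- cbind(0L, 0L)
  if (radius >= 1L) {
    for (dj in seq_len(radius)) {
      di <- -dj:dj
      if (direction %in% c("up", "both"))
        off <- rbind(off, cbind(di, dj))
      if (direction %in% c("down", "both"))
        off <- rbind(off, cbind(di, -dj))
    }
  }
  off
}

#' Dilate a mask with an in-plane triangular structuring element
#'
#' The element of radius `r` is the origin plus rows of width `2*j + 1` at
#' PE offsets `j = 1..r` (a discrete triangle with its apex at the origin).
#' `direction = "both"` unions the triangle with its PE reflection, so the
#' dilation over-covers displacements of either sign.
#'
#' @param mask logical array
#' @param radius element radius in voxels (0 = identity)
#' @param direction `"up"`, `"down"`, or `"both"`
#' @param pe_axis phase-encode axis (the element's long axis)
#' @return dilated logical mask (a superset of `mask`)
#' @export
dilate_mask <- function(mask, radius = 2L, direction = c("up", "down", "both"),
                        pe_axis = 2L) {
  direction <- match.arg(direction)
  if (!any(mask)) stop("cannot dilate an empty mask")
  if (radius == 0L) return(mask)
  orig <- mask
  m <- as_vol(mask)
  ro_axis <- if (pe_axis == 1L) 2L else 1L
  offs <- triangle_offsets(radius, direction)
  out <- m
  for (r in seq_len(nrow(offs))) {
    out <- out | shift_axis(shift_axis(m, ro_axis, offs[r, 1]),
                            pe_axis, offs[r, 2])
  }
  restore_dim(out, orig)
}

#' Warp a mask along the phase-encode axis with a field map
#'
#' Resamples the mask by the displacement `-factor * field *
#' total_readout_time` (nearest neighbour, re-binarized).  With
#' `factor = 2` this maps a blip-up mask onto blip-down geometry, since the
#' two images are displaced by `+d` and `-d` respectively.
#'
#' @param mask logical array
#' @param field a [field_map()] in Hz
#' @param factor displacement multiplier (0 = identity)
#' @param params an [acq_params()]
#' @return warped logical mask
#' @export
warp_mask <- function(mask, field, factor, params) {
  d <- field_displacement(field, params)
  out <- pe_resample(array(as.numeric(mask), dim(mask)), factor * d,
                     params$pe_axis, "nearest") > 0.5
  dim(out) <- dim(mask)
  out
}
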