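#' Preprocessing configuration
#'
#' Defaults follow the standard contrast-enhanced thoracic protocol: clip to
#' \[-125, 225\] HU, resample to 1 mm isotropic voxels, and discretize with a
#' fixed 5-HU bin width, giving (225 - (-125)) / 5 = 70 bins.
#'
#' @param clip_lo,clip_hi Clipping window in HU.
#' @param bin_width Discretization bin width in HU; must divide the window.
#' @param target_spacing Target isotropic voxel spacing in mm (length 3).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(clip_lo = -125, clip_hi = 225, bin_width = 5,
                              target_spacing = c(1, 1, 1)) {
  if (clip_lo >= clip_hi) stop("clip_lo must be below clip_hi")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (abs((clip_hi - clip_lo) %% bin_width) > 1e-9)
    stop("(clip_hi - clip_lo) must be divisible by bin_width")
  structure(list(clip_lo = clip_lo, clip_hi = clip_hi, bin_width = bin_width,
                 target_spacing = as.numeric(target_spacing),
                 n_bins = as.integer(round((clip_hi - clip_lo) / bin_width))),
            class = "preprocess_config")
}

#' Clip Hounsfield units to the analysis window
#'
#' Values below `clip_lo` map to `clip_lo`, above `clip_hi` to `clip_hi`;
#' in-window values are untouched. Idempotent.
#'
#' @param vol A `ct_volume`.
#' @param cfg A [preprocess_config()].
#' @return Clipped `ct_volume`.
#' @export
clip_hu <- function(vol, cfg = preprocess_config()) {
  v <- pmin(pmax(vol$values, cfg$clip_lo), cfg$clip_hi)
  dim(v) <- dim(vol$values)
  ct_volume(v, vol$spacing, vol$origin)
}

#' Resample an image/mask pair to isotropic spacing
#'
#' The image is interpolated trilinearly, the mask with nearest-neighbor so it
#' stays binary. Output grid size per axis is `round(n * spacing / target)`.
#'
#' @inheritParams clip_hu
#' @param mask A `mask_volume` on the same grid.
#' @return List with resampled `vol` and `mask`.
#' @export
resample_isotropic <- function(vol, mask, cfg = preprocess_config()) {
  check_aligned(vol, mask)
  target <- cfg$target_spacing
  if (any(target <= 0)) stop("degenerate target spacing")
  d_in <- dim(vol$values)
  d_out <- pmax(as.integer(round(d_in * vol$spacing / target)), 1L)
  if (all(d_out == d_in) && max(abs(vol$spacing - target)) < 1e-9)
    return(list(vol = vol, mask = mask))
  # voxel-center aligned source coordinates (1-based, fractional)
  src <- lapply(1:3, function(ax) {
    (seq_len(d_out[ax]) - 0.5) * target[ax] / vol$spacing[ax] + 0.5
  })
  v_out <- trilinear_sample(vol$values, src[[1]], src[[2]], src[[3]])
  m_out <- nearest_sample(mask$values, src[[1]], src[[2]], src[[3]])
  list(vol = ct_volume(v_out, target, vol$origin),
       mask = mask_volume(m_out, target, mask$origin))
}

trilinear_sample <- function(arr, xs, ys, zs) {
  d <- dim(arr)
  clampf <- function(v, n) pmin(pmax(v, 1), n)
  xs <- clampf(xs, d[1]); ys <- clampf(ys, d[2]); zs <- clampf(zs, d[3])
  x0 <- pmin(floor(xs), d[1] - 1); fx <- xs - x0
  y0 <- pmin(floor(ys), d[2] - 1); fy <- ys - y0
  z0 <- pmin(floor(zs), d[3] - 1); fz <- zs - z0
  if (d[1] == 1) { x0 <- rep(1, length(xs)); fx <- rep(0, length(xs)) }
  if (d[2] == 1) { y0 <- rep(1, length(ys)); fy <- rep(0, length(ys)) }
  if (d[3] == 1) { z0 <- rep(1, length(zs)); fz <- rep(0, length(zs)) }
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  out <- array(0, c(nx, ny, nz))
  FX <- array(fx, c(nx, ny, nz))
  FY <- array(rep(fy, each = nx), c(nx, ny, nz))
  FZ <- array(rep(fz, each = nx * ny), c(nx, ny, nz))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- pmin(x0 + cx, d[1]); iy <- pmin(y0 + cy, d[2]); iz <- pmin(z0 + cz, d[3])
    w <- (if (cx) FX else 1 - FX) * (if (cy) FY else 1 - FY) *
         (if (cz) FZ else 1 - FZ)
    out <- out + w * arr[cbind(rep(ix, times = ny * nz),
                               rep(rep(iy, each = nx), times = nz),
                               rep(iz, each = nx * ny))]
  }
  out
}

nearest_sample <- function(arr, xs, ys, zs) {
  d <- dim(arr)
  ix <- pmin(pmax(round(xs), 1), d[1])
  iy <- pmin(pmax(round(ys), 1), d[2])
  iz <- pmin(pmax(round(zs), 1), d[3])
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  out <- arr[cbind(rep(ix, times = ny * nz),
                   rep(rep(iy, each = nx), times = nz),
                   rep(iz, each = nx * ny))]
  array(out, c(nx, ny, nz))
}

#' Discretize clipped HU values into fixed-width bins over the ROI
#'
#' Bin index of value x is `floor((x - clip_lo) / bin_width) + 1`, capped at
#' `n_bins` so the top edge `clip_hi` falls in the last bin (half-open bins,
#' closed at the top). Voxels outside the mask get bin 0.
#'
#' @inheritParams resample_isotropic
#' @return List with `binned` (integer array, 0 outside ROI) and `n_bins`.
#' @export
discretize <- function(vol, mask, cfg = preprocess_config()) {
  check_aligned(vol, mask)
  b <- floor((vol$values - cfg$clip_lo) / cfg$bin_width) + 1
  b <- pmin(pmax(b, 1), cfg$n_bins)
  b <- as.integer(b) * as.integer(mask$values)
  dim(b) <- dim(vol$values)
  list(binned = b, n_bins = cfg$n_bins)
}

#' Discretize an arbitrary derived image over a ROI with a fixed bin count
#'
#' Derived (filtered) images are not on the HU scale, so they are binned with
#' a fixed number of equal-width bins spanning the in-ROI range.
#'
#' @param values Numeric array.
#' @param mask_values Integer 0/1 array on the same grid.
#' @param n_bins Number of equal-width bins.
#' @return Integer array of bin labels, 0 outside the ROI.
#' @export
discretize_fixed_count <- function(values, mask_values, n_bins = 32L) {
  inroi <- values[mask_values == 1L]
  lo <- min(inroi); hi <- max(inroi)
  if (hi - lo < 1e-12) {
    b <- array(1L, dim(values))
  } else {
    w <- (hi - lo) / n_bins
    b <- floor((values - lo) / w) + 1
    b <- pmin(pmax(b, 1), n_bins)
  }
  out <- as.integer(b) * as.integer(mask_values)
  dim(out) <- dim(values)
  out
}
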