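# Low-level volume operations shared by every assay pipeline. Filters act
# plane-wise in 2-D (matching per-plane confocal acquisition); the Gaussian
# kernel follows the Matlab fspecial convention: an N x N truncated kernel
# normalised to sum 1, with replicate padding at image borders and the kernel
# origin at element floor((N+1)/2) so even sizes are supported.

#' Build a 1-D truncated, normalised Gaussian kernel
#'
#' The full 2-D kernel is the outer product of this vector with itself, which
#' is how the plane-wise filters apply it (separably).
#'
#' @param size Kernel side length in pixels (>= 1).
#' @param sigma Standard deviation in pixels (> 0).
#' @return Numeric vector of length `size`, summing to 1.
#' @export
gaussian_kernel1d <- function(size, sigma) {
  if (size < 1) stop("kernel size must be >= 1")
  if (sigma <= 0) stop("sigma must be > 0")
  x <- seq_len(size) - (size + 1) / 2   # half-integer grid for even sizes
  u <- exp(-x^2 / (2 * sigma^2))
  u / sum(u)
}

apply_sep_filter <- function(vol, kernel1d) {
  vol <- as_volume(vol)
  out <- conv_sep_cpp(as.numeric(vol), dim(vol), kernel1d)
  array(out, dim = dim(vol))
}

#' Plane-wise Gaussian low-pass filter
#'
#' Each z-plane is convolved independently with a `size` x `size` truncated
#' Gaussian of standard deviation `sigma`, normalised to sum 1 (so constants
#' are preserved).
#'
#' @param vol 3-D numeric array (or matrix).
#' @param size Kernel side length in pixels.
#' @param sigma Kernel standard deviation in pixels.
#' @return Filtered volume, same shape as `vol`.
#' @export
gaussian_lowpass <- function(vol, size, sigma) {
  apply_sep_filter(vol, gaussian_kernel1d(size, sigma))
}

#' Plane-wise difference of Gaussians
#'
#' Band-pass enhancement used before thresholding throughout the assay
#' pipelines: the background blur (large sigma) is subtracted from the
#' foreground blur (small sigma). Signed values are retained.
#'
#' @param vol 3-D numeric array.
#' @param fg_size,fg_sigma Foreground kernel side length / standard deviation.
#' @param bg_size,bg_sigma Background kernel side length / standard deviation.
#' @return Signed filtered volume, same shape as `vol`.
#' @export
difference_of_gaussians <- function(vol, fg_size, fg_sigma, bg_size, bg_sigma) {
  if (fg_sigma >= bg_sigma)
    stop("foreground sigma must be smaller than background sigma")
  gaussian_lowpass(vol, fg_size, fg_sigma) - gaussian_lowpass(vol, bg_size, bg_sigma)
}

#' Plane-wise mean filter over a square window
#'
#' @param vol 3-D numeric array.
#' @param side Window side length in pixels (>= 1).
#' @return Filtered volume, same shape as `vol`.
#' @export
average_filter <- function(vol, side) {
  if (side < 1) stop("window side must be >= 1")
  apply_sep_filter(vol, rep(1 / side, side))
}

#' Maximum-intensity projection over z
#'
#' @param vol 3-D numeric array.
#' @return Matrix of per-(y, x) maxima over all planes.
#' @export
max_project <- function(vol) {
  vol <- as_volume(vol)
  out <- vol[, , 1]
  nz <- dim(vol)[3]
  if (nz > 1) for (z in 2:nz) out <- pmax(out, vol[, , z])
  out
}

#' Label connected components of a 3-D mask
#'
#' @param mask 3-D logical array.
#' @param connectivity 26 (default) or 6.
#' @return Integer array of component labels (0 = background), labelled in
#'   column-major scan order.
#' @export
label_components <- function(mask, connectivity = 26) {
  mask <- as_mask(mask)
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  array(label3d_cpp(as.logical(mask), dim(mask), as.integer(connectivity)),
        dim = dim(mask))
}

#' Keep connected components by voxel count
#'
#' Retains components whose size lies in `[min_px, max_px]` inclusive (the
#' rule "components with less than N pixels were removed" keeps exactly-N
#' components).
#'
#' @param mask 3-D logical array.
#' @param min_px Minimum component size (voxels).
#' @param max_px Maximum component size; `Inf` for no upper bound.
#' @param connectivity 26 (default) or 6.
#' @return Filtered mask, a subset of `mask`.
#' @export
filter_components_by_size <- function(mask, min_px, max_px = Inf, connectivity = 26) {
  if (min_px < 0) stop("min_px must be >= 0")
  if (min_px > max_px) stop("min_px must not exceed max_px")
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n == 0L) return(as_mask(mask) & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  keep <- which(sizes >= min_px & sizes <= max_px)
  out <- array(lab %in% keep, dim = dim(lab))
  out
}

#' 6-connected 3-D erosion with surface extraction
#'
#' Erodes with the structuring element formed by a centre voxel and its six
#' face neighbours; voxels outside the volume count as background, so border
#' voxels always erode. The surface is the set difference between the mask
#' and its erosion, so `eroded` and `surface` partition `mask`.
#'
#' @param mask 3-D logical array.
#' @return List with logical arrays `eroded` and `surface`.
#' @export
erode_with_surface <- function(mask) {
  mask <- as_mask(mask)
  er <- mask &
    shift_mask(mask,  1L, 0L, 0L) & shift_mask(mask, -1L, 0L, 0L) &
    shift_mask(mask, 0L,  1L, 0L) & shift_mask(mask, 0L, -1L, 0L) &
    shift_mask(mask, 0L, 0L,  1L) & shift_mask(mask, 0L, 0L, -1L)
  list(eroded = er, surface = mask & !er)
}

#' Morphological reconstruction of a mask from seed markers
#'
#' Returns the union of connected components of `limit` that contain at least
#' one seed voxel (geodesic reconstruction by dilation, run to stability).
#' Seed voxels outside `limit` are ignored.
#'
#' @param seed,limit 3-D logical arrays of the same shape.
#' @param connectivity 26 (default) or 6.
#' @return Reconstructed mask, a subset of `limit`.
#' @export
reconstruct_mask <- function(seed, limit, connectivity = 26) {
  seed <- as_mask(seed); limit <- as_mask(limit)
  if (!identical(dim(seed), dim(limit))) stop("seed and limit must share shape")
  lab <- label_components(limit, connectivity)
  hit <- unique(lab[seed & limit])
  hit <- hit[hit > 0L]
  array(lab %in% hit, dim = dim(limit))
}

# ---- 2-D binary morphology helpers (chip segmentation) ----------------------

disk_brush <- function(radius) EBImage::makeBrush(2L * radius + 1L, shape = "disc")

erode2d <- function(mask2d, brush) {
  EBImage::erode(mask2d * 1, brush) > 0.5
}

dilate2d <- function(mask2d, brush) {
  EBImage::dilate(mask2d * 1, brush) > 0.5
}

open2d <- function(mask2d, brush) {
  EBImage::opening(mask2d * 1, brush) > 0.5
}

# Windowed extreme along rows (vertical rod of height `window`, width 1).
# Out-of-image rows are ignored: erosion behaves as if padded with foreground,
# dilation as if padded with background (the Matlab imerode/imdilate default).
run_extreme_rows <- function(m, window, op = c("min", "max")) {
  op <- match.arg(op)
  if (window %% 2L != 1L) stop("rod height must be odd")
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(m)
  fill <- if (op == "min") Inf else -Inf
  f <- if (op == "min") pmin else pmax
  pad <- matrix(fill, h, ncol(m))
  a <- rbind(pad, m, pad)
  len <- 1L
  while (len * 2L <= window) {
    n <- nrow(a)
    shifted <- rbind(a[(len + 1L):n, , drop = FALSE], matrix(fill, len, ncol(a)))
    a <- f(a, shifted)
    len <- len * 2L
  }
  rest <- window - len
  res <- if (rest > 0L) {
    n <- nrow(a)
    shifted <- rbind(a[(rest + 1L):n, , drop = FALSE], matrix(fill, rest, ncol(a)))
    f(a, shifted)
  } else a
  res[seq_len(nrow(m)), , drop = FALSE]
}

rod_erode_rows <- function(mask2d, height) {
  run_extreme_rows(mask2d * 1, as.integer(height), "min") > 0.5
}

rod_dilate_rows <- function(mask2d, height) {
  run_extreme_rows(mask2d * 1, as.integer(height), "max") > 0.5
}

# 2-D component labelling / size filter on matrices (8-connectivity)
label2d <- function(mask2d) {
  lab <- label_components(array(mask2d, dim = c(dim(mask2d), 1L)), 26)
  lab[, , 1]
}

filter_size2d <- function(mask2d, min_px, max_px = Inf) {
  m <- filter_components_by_size(array(mask2d, dim = c(dim(mask2d), 1L)),
                                 min_px, max_px, 26)
  m[, , 1]
}

# ---- mosaic stitching -------------------------------------------------------

#' Stitch a grid of overlapping image fields into one volume
#'
#' Integer (y, x) offsets between adjacent fields are estimated at the argmax
#' of the normalised cross-correlation over the nominal overlap strips of the
#' fields' maximum projections, searched within +/- `search_frac` of the
#' nominal overlap around the nominal offset; fields are then placed by
#' translation only. Overlapping voxels take the maximum of contributing
#' tiles by default (preserving puncta); `blend = "feather"` uses
#' distance-weighted averaging instead.
#'
#' @param fields List of 3-D arrays, all the same shape, in row-major grid
#'   order.
#' @param grid_rows,grid_cols Mosaic layout; `grid_rows * grid_cols` must
#'   equal `length(fields)`.
#' @param overlap Nominal overlap in pixels, length 1 or 2 (`c(y, x)`).
#' @param search_frac Search window half-width as a fraction of the overlap.
#' @param blend `"max"` or `"feather"`.
#' @return List with `volume` (stitched array), `positions` (matrix of 0-based
#'   top-left (y, x) placements per field) and `fallback` (logical per field,
#'   `TRUE` where a zero-variance strip forced the nominal offset).
#' @export
stitch_mosaic <- function(fields, grid_rows, grid_cols, overlap,
                          search_frac = 0.25, blend = c("max", "feather")) {
  blend <- match.arg(blend)
  if (length(fields) < 1L) stop("need at least one field")
  fields <- lapply(fields, as_volume)
  if (grid_rows * grid_cols != length(fields))
    stop("grid layout does not match the number of fields")
  d <- dim(fields[[1]])
  if (!all(vapply(fields, function(f) identical(dim(f), d), logical(1))))
    stop("all fields must share the same shape")
  overlap <- rep_len(as.integer(overlap), 2L)
  if (length(fields) > 1L && any(overlap < 1L)) stop("overlap strip is empty")

  projs <- lapply(fields, max_project)
  positions <- matrix(0L, length(fields), 2L)   # 0-based (y, x)
  fallback <- logical(length(fields))

  idx <- function(r, c) (r - 1L) * grid_cols + c
  for (r in seq_len(grid_rows)) {
    for (c in seq_len(grid_cols)) {
      i <- idx(r, c)
      if (r == 1L && c == 1L) next
      if (c > 1L) {            # register against left neighbour
        j <- idx(r, c - 1L)
        nominal <- positions[j, ] + c(0L, d[2] - overlap[2])
        est <- ncc_register(projs[[j]], projs[[i]],
                            rel_nominal = c(0L, d[2] - overlap[2]),
                            overlap = overlap, axis = "x",
                            search_frac = search_frac)
      } else {                 # first column: register against tile above
        j <- idx(r - 1L, c)
        nominal <- positions[j, ] + c(d[1] - overlap[1], 0L)
        est <- ncc_register(projs[[j]], projs[[i]],
                            rel_nominal = c(d[1] - overlap[1], 0L),
                            overlap = overlap, axis = "y",
                            search_frac = search_frac)
      }
      positions[i, ] <- positions[j, ] + est$offset
      fallback[i] <- est$fallback
    }
  }
  positions[, 1] <- positions[, 1] - min(positions[, 1])
  positions[, 2] <- positions[, 2] - min(positions[, 2])

  ny <- max(positions[, 1]) + d[1]
  nx <- max(positions[, 2]) + d[2]
  if (blend == "max") {
    out <- array(-Inf, dim = c(ny, nx, d[3]))
    for (i in seq_along(fields)) {
      ys <- positions[i, 1] + seq_len(d[1]); xs <- positions[i, 2] + seq_len(d[2])
      out[ys, xs, ] <- pmax(out[ys, xs, , drop = FALSE], fields[[i]])
    }
    out[!is.finite(out)] <- 0
  } else {
    acc <- array(0, dim = c(ny, nx, d[3]))
    wacc <- array(0, dim = c(ny, nx, d[3]))
    wy <- pmin(seq_len(d[1]), rev(seq_len(d[1])))
    wx <- pmin(seq_len(d[2]), rev(seq_len(d[2])))
    w <- outer(wy, wx, pmin)
    for (i in seq_along(fields)) {
      ys <- positions[i, 1] + seq_len(d[1]); xs <- positions[i, 2] + seq_len(d[2])
      wv <- array(w, dim = d)
      acc[ys, xs, ] <- acc[ys, xs, , drop = FALSE] + fields[[i]] * wv
      wacc[ys, xs, ] <- wacc[ys, xs, , drop = FALSE] + wv
    }
    out <- acc / pmax(wacc, .Machine$double.eps)
  }
  list(volume = out, positions = positions, fallback = fallback)
}

# NCC registration of tile b against tile a, sharing shape; rel_nominal is the
# nominal 0-based (y, x) offset of b relative to a.
ncc_register <- function(a, b, rel_nominal, overlap, axis, search_frac) {
  d <- dim(a)
  ov <- if (axis == "x") overlap[2] else overlap[1]
  w <- max(1L, as.integer(round(search_frac * ov)))
  best <- c(0L, 0L); best_ncc <- -Inf; any_valid <- FALSE
  for (sy in -w:w) {
    for (sx in -w:w) {
      off <- rel_nominal + c(sy, sx)
      ya <- max(1L, 1L + off[1]):min(d[1], d[1] + off[1])
      xa <- max(1L, 1L + off[2]):min(d[2], d[2] + off[2])
      if (length(ya) < 2L || length(xa) < 2L) next
      pa <- a[ya, xa]
      pb <- b[ya - off[1], xa - off[2]]
      if (sd(pa) == 0 || sd(pb) == 0) next
      any_valid <- TRUE
      ncc <- cor(as.numeric(pa), as.numeric(pb))
      better <- ncc > best_ncc + 1e-12 ||
        (abs(ncc - best_ncc) <= 1e-12 &&
           sum(abs(c(sy, sx))) < sum(abs(best - rel_nominal)))
      if (better) { best_ncc <- ncc; best <- off }
    }
  }
  if (!any_valid) {
    warning("zero-variance overlap strip; falling back to nominal offset")
    return(list(offset = rel_nominal, fallback = TRUE))
  }
  list(offset = best, fallback = FALSE)
}
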