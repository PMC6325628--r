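# Core containers: volumes, masks, channel stacks.
#
# A Volume is a plain 3-D numeric array laid out [y, x, z]: dim 1 runs down
# the image (rows), dim 2 runs left-to-right (columns), dim 3 is the axial
# plane index with z = 1 the bottom-most acquired plane. Intensities are raw
# gray levels (dimensionless, >= 0). Masks are logical arrays of the same
# shape. Device (chip) masks are kept in 2-D until projected to planes.

#' Validate and normalise a 3-D intensity volume
#'
#' Accepts a 2-D matrix (promoted to a single-plane volume) or a 3-D array.
#' Layout is `[y, x, z]` with `z = 1` the bottom-most plane.
#'
#' @param data Numeric matrix or 3-D array of raw gray levels.
#' @return A 3-D numeric array.
#' @export
as_volume <- function(data) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("a volume must be a 2-D matrix or 3-D array")
  if (!is.numeric(data)) stop("volume intensities must be numeric")
  if (any(dim(data) < 1L)) stop("all volume dimensions must be >= 1")
  if (anyNA(data) || any(data < 0)) stop("volume intensities must be finite and >= 0")
  data
}

#' Validate a mask volume
#'
#' @param data Logical matrix or 3-D array.
#' @return A 3-D logical array (a matrix is promoted to one plane).
#' @export
as_mask <- function(data) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("a mask must be a 2-D matrix or 3-D array")
  if (!is.logical(data)) {
    if (!all(data %in% c(0, 1))) stop("mask values must be logical or 0/1")
    data <- array(as.logical(data), dim = dim(data))
  }
  data
}

#' Bundle the channels of one bioreactor acquisition
#'
#' @param channels Named list of volumes, all the same shape. Expected names
#'   per assay: morphometric `hoechst`, `tuj1`, `th`, `marker647`;
#'   mitochondrial `hoechst`, `mitotracker`, `tmrm`, `cellmask`;
#'   viability `hoechst`, `calcein`, `eh`, `cc3`.
#' @param assay One of `"morpho"`, `"mito"`, `"viability"`.
#' @param meta Optional named list of bioreactor metadata (line, genotype,
#'   background, treatment, timepoint).
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, assay = c("morpho", "mito", "viability"),
                          meta = list()) {
  assay <- match.arg(assay)
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list")
  channels <- lapply(channels, as_volume)
  dims <- vapply(channels, function(v) paste(dim(v), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) stop("all channels must share the same shape")
  structure(list(channels = channels, assay = assay, meta = meta),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack: %s assay, %d channel(s) [%s], %d x %d x %d>\n",
              x$assay, length(x$channels),
              paste(names(x$channels), collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}

stack_channel <- function(stack, name) {
  if (!name %in% names(stack$channels))
    stop(sprintf("channel '%s' missing from %s stack", name, stack$assay))
  stack$channels[[name]]
}

#' Read a volume from a multi-page TIFF file
#'
#' Pages are interpreted as z-planes (page 1 = bottom plane). Intensities are
#' rescaled from the TIFF unit interval by `scale`, so raw gray levels written
#' with [write_volume_tiff()] round-trip.
#'
#' @param path Path to a TIFF file.
#' @param scale Gray-level value mapped to TIFF intensity 1.0.
#' @return A 3-D numeric array.
#' @export
read_volume_tiff <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  vol <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (z in seq_along(pages)) vol[, , z] <- pages[[z]]
  as_volume(vol * scale)
}

#' Write a volume (or mask) to a 16-bit multi-page TIFF file
#'
#' @param vol 3-D numeric or logical array.
#' @param path Output path.
#' @param scale Gray level mapped to full intensity; values are clipped.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(vol, path, scale = 65535) {
  if (is.logical(vol)) vol <- vol * 1
  vol <- as_volume(vol)
  pages <- lapply(seq_len(dim(vol)[3]),
                  function(z) pmin(vol[, , z] / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# logical shift of a 3-D array by (dy, dx, dz) with constant fill
shift_mask <- function(mask, dy = 0L, dx = 0L, dz = 0L, fill = FALSE) {
  d <- dim(mask)
  out <- array(fill, dim = d)
  ys <- seq_len(d[1]); xs <- seq_len(d[2]); zs <- seq_len(d[3])
  ysrc <- ys - dy; xsrc <- xs - dx; zsrc <- zs - dz
  keep_y <- ysrc >= 1 & ysrc <= d[1]
  keep_x <- xsrc >= 1 & xsrc <= d[2]
  keep_z <- zsrc >= 1 & zsrc <= d[3]
  if (!any(keep_y) || !any(keep_x) || !any(keep_z)) return(out)
  out[ys[keep_y], xs[keep_x], zs[keep_z]] <-
    mask[ysrc[keep_y], xsrc[keep_x], zsrc[keep_z]]
  out
}

bind_meta <- function(meta, feats) {
  if (length(meta) == 0L) return(feats)
  cbind(as.data.frame(meta, stringsAsFactors = FALSE), feats)
}
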