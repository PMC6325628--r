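# Segmentation of the microfluidic device: the device ("OrganoPlate") mask,
# the central phase guide, and the flanking Matrigel (MC) and perfusion (PC)
# channels. All device work happens on 2-D maximum projections; the final
# masks are projected to planes, with the phase guide clipped to the lowest
# eight z-planes (z = 1 is the bottom-most acquired plane).

#' Container for the chip-structure masks of one bioreactor
#'
#' @param device 2-D logical matrix: device structures (walls + phase guide).
#'   Cellular masks must exclude these pixels.
#' @param phaseguide 2-D logical matrix, subset of `device`.
#' @param mc,pc 2-D logical matrices: Matrigel and perfusion channels, both
#'   disjoint subsets of the complement of `device`.
#' @param nz Number of z-planes of the parent stack.
#' @param pg_zmax Highest plane (1-based) occupied by the phase guide.
#' @return An object of class `chip_masks`.
#' @export
chip_masks <- function(device, phaseguide, mc, pc, nz, pg_zmax = 8L) {
  stopifnot(is.matrix(device), is.matrix(phaseguide), is.matrix(mc), is.matrix(pc))
  if (any(phaseguide & !device)) stop("phase guide must lie inside the device mask")
  if (any(mc & pc)) stop("MC and PC must be disjoint")
  if (any(mc & device) || any(pc & device))
    stop("MC and PC must lie outside the device mask")
  structure(list(device = device, phaseguide = phaseguide, mc = mc, pc = pc,
                 nz = as.integer(nz), pg_zmax = as.integer(pg_zmax)),
            class = "chip_masks")
}

#' @export
print.chip_masks <- function(x, ...) {
  cat(sprintf(paste0("<chip_masks: %d x %d x %d; device %d px, phase guide %d px",
                     " (z <= %d), MC %d px, PC %d px>\n"),
              nrow(x$device), ncol(x$device), x$nz, sum(x$device),
              sum(x$phaseguide), x$pg_zmax, sum(x$mc), sum(x$pc)))
  invisible(x)
}

#' Project the 2-D device mask to all z-planes
#'
#' Wall blocks span every plane; the phase guide is clipped to the lowest
#' `pg_zmax` planes, mirroring its physical height.
#'
#' @param chip A [chip_masks] object.
#' @return 3-D logical array of device voxels.
#' @export
chip_device_3d <- function(chip) {
  walls <- chip$device & !chip$phaseguide
  out <- array(FALSE, dim = c(dim(chip$device), chip$nz))
  for (z in seq_len(chip$nz)) {
    out[, , z] <- walls
    if (z <= chip$pg_zmax) out[, , z] <- out[, , z] | chip$phaseguide
  }
  out
}

#' Identify the phase guide among the device blocks
#'
#' The refined 2-D device mask must contain exactly three connected
#' components; ordered left to right by their minimum column, the middle
#' block is the phase guide (ordering is by position, never by size).
#'
#' @param device_mask_2d 2-D logical matrix.
#' @return 2-D logical matrix containing only the middle block.
#' @export
detect_phaseguide <- function(device_mask_2d) {
  lab <- label2d(device_mask_2d)
  n <- max(lab)
  if (n != 3L)
    stop(sprintf("phase-guide ambiguity: expected 3 device blocks, found %d", n))
  min_col <- vapply(seq_len(n), function(k) min(col(lab)[lab == k]), numeric(1))
  mid <- order(min_col)[2]
  lab == mid
}

#' Derive the Matrigel and perfusion channel masks
#'
#' Both channels are reconstructed inside the complement of the device mask.
#' The MC seed extends the phase guide one pixel toward smaller x (left), the
#' PC seed one pixel toward larger x (right), so the MC always lies left of
#' the phase guide and the PC right of it.
#'
#' @param phaseguide 2-D logical matrix (non-empty).
#' @param device_mask 2-D logical matrix.
#' @return List with 2-D logical matrices `mc` and `pc`.
#' @export
derive_channels <- function(phaseguide, device_mask) {
  if (!any(phaseguide)) stop("phase guide mask is empty")
  pg3 <- array(phaseguide, dim = c(dim(phaseguide), 1L))
  limit <- array(!device_mask, dim = c(dim(device_mask), 1L))
  seed_mc <- (pg3 | shift_mask(pg3, dx = -1L)) & limit
  seed_pc <- (pg3 | shift_mask(pg3, dx = 1L)) & limit
  mc <- reconstruct_mask(seed_mc, limit)[, , 1]
  pc <- reconstruct_mask(seed_pc, limit)[, , 1]
  if (!any(mc)) warning("Matrigel-channel reconstruction is empty (chip edge?)")
  if (!any(pc)) warning("perfusion-channel reconstruction is empty (chip edge?)")
  list(mc = mc, pc = pc)
}

# Shared refinement chain that turns a rough 2-D device mask into wall/phase
# guide blocks: erode r5 -> drop small components -> dilate r20 -> close
# vertical gaps with a tall rod dilation -> remove non-wall structures with a
# taller rod erosion -> drop sub-wall components (-> optional opening and
# final dilation for the cell-death recipe). Rod heights may exceed the image;
# out-of-image pixels are ignored (erosion pads with foreground, dilation
# with background), so only structures spanning the full image height survive
# an over-height erosion rod.
refine_chip_mask <- function(rough, erode_r = 5L, min_component_px = 1000,
                             dilate_r = 20L, rod_dilate_h = 101L,
                             rod_erode_h = 501L, min_final_px = 1e5,
                             opening_r = NULL, final_dilate_r = NULL) {
  m <- erode2d(rough, disk_brush(erode_r))
  m <- filter_size2d(m, min_component_px)
  if (!any(m)) stop("chip not found: no component survived the small-component filter")
  m <- dilate2d(m, disk_brush(dilate_r))
  m <- rod_dilate_rows(m, rod_dilate_h)
  m <- rod_erode_rows(m, rod_erode_h)
  m <- filter_size2d(m, min_final_px)
  if (!any(m)) stop("chip not found: no component survived the wall-size filter")
  if (!is.null(opening_r)) m <- open2d(m, disk_brush(opening_r))
  if (!is.null(final_dilate_r)) m <- dilate2d(m, disk_brush(final_dilate_r))
  m
}

finish_chip <- function(device2d, nz, pg_zmax) {
  pg <- detect_phaseguide(device2d)
  ch <- derive_channels(pg, device2d)
  chip_masks(device2d, pg, ch$mc, ch$pc, nz = nz, pg_zmax = pg_zmax)
}

#' Segment the chip for the morphometric (immunofluorescence) assay
#'
#' A rough device mask is built from per-channel intensity thresholds on
#' size-5 average-filtered maximum projections (channels combined by OR),
#' then refined with the standard chain (erosion r5, component filter,
#' dilation r20, vertical rod dilation 101 x 1, rod erosion 501 x 1,
#' wall-size filter), followed by phase-guide detection and MC/PC
#' reconstruction.
#'
#' @param stack A [channel_stack] for the `morpho` assay.
#' @param rough_thresholds Named numeric vector of per-channel gray-level
#'   thresholds for the rough mask. The raw data carry no absolute device
#'   gray level, so these are configuration; defaults suit the synthetic
#'   fixtures.
#' @param min_component_px,min_wall_px Component-size cut-offs of the
#'   refinement chain (pixels).
#' @param pg_zmax Highest plane occupied by the phase guide.
#' @return A [chip_masks] object.
#' @export
segment_chip_morphometric <- function(stack,
                                      rough_thresholds = c(hoechst = 20, tuj1 = 20,
                                                           th = 20, marker647 = 20),
                                      min_component_px = 1000,
                                      min_wall_px = 1e5,
                                      pg_zmax = 8L) {
  chans <- intersect(names(rough_thresholds), names(stack$channels))
  if (length(chans) == 0L) stop("no rough-threshold channel present in the stack")
  d <- dim(stack$channels[[1]])
  rough <- matrix(FALSE, d[1], d[2])
  for (ch in chans) {
    proj <- max_project(average_filter(stack$channels[[ch]], 5))
    rough <- rough | (proj > rough_thresholds[[ch]])
  }
  dev2d <- refine_chip_mask(rough, min_component_px = min_component_px,
                            min_final_px = min_wall_px)
  finish_chip(dev2d, nz = d[3], pg_zmax = pg_zmax)
}

#' Segment the chip for the mitochondrial (live-dye) assay
#'
#' The rough mask uses the fixed gray-level rule
#' `(10 < TMRMmax < 30) OR ((30 < Hoechstmax < 200) AND (MitoTrackermax > 15))`
#' on size-5 average-filtered maximum projections; refinement then follows
#' the morphometric chain.
#'
#' @param stack A [channel_stack] for the `mito` assay.
#' @param rule Operator grouping of the printed rule: the default binds the
#'   Hoechst range to the MitoTracker condition; `"range_or_and_mito"`
#'   applies the AND to both intensity ranges.
#' @inheritParams segment_chip_morphometric
#' @return A [chip_masks] object.
#' @export
segment_chip_mito <- function(stack,
                              rule = c("tmrm_or_nuclear_and_mito",
                                       "range_or_and_mito"),
                              min_component_px = 1000, min_wall_px = 1e5,
                              pg_zmax = 8L) {
  rule <- match.arg(rule)
  tmrm <- max_project(average_filter(stack_channel(stack, "tmrm"), 5))
  hoe <- max_project(average_filter(stack_channel(stack, "hoechst"), 5))
  mito <- max_project(average_filter(stack_channel(stack, "mitotracker"), 5))
  rough <- if (rule == "tmrm_or_nuclear_and_mito") {
    (tmrm > 10 & tmrm < 30) | ((hoe > 30 & hoe < 200) & (mito > 15))
  } else {
    ((tmrm > 10 & tmrm < 30) | (hoe > 30 & hoe < 200)) & (mito > 15)
  }
  d <- dim(stack$channels[[1]])
  dev2d <- refine_chip_mask(rough, min_component_px = min_component_px,
                            min_final_px = min_wall_px)
  finish_chip(dev2d, nz = d[3], pg_zmax = pg_zmax)
}

#' Segment the chip for the cell-death (calcein) assay
#'
#' The rough mask is `50 < Calceinmax < 300` on the size-5 average-filtered
#' maximum projection. Refinement uses the standard chain with taller rods
#' (dilation 201 x 1, erosion 3001 x 1) and finishes with a morphological
#' opening (disk r20) and dilation (disk r22).
#'
#' @param stack A [channel_stack] for the `viability` assay.
#' @inheritParams segment_chip_morphometric
#' @return A [chip_masks] object.
#' @export
segment_chip_celldeath <- function(stack, min_component_px = 1000,
                                   min_wall_px = 1e5, pg_zmax = 8L) {
  cal <- max_project(average_filter(stack_channel(stack, "calcein"), 5))
  rough <- cal > 50 & cal < 300
  d <- dim(stack$channels[[1]])
  dev2d <- refine_chip_mask(rough, min_component_px = min_component_px,
                            rod_dilate_h = 201L, rod_erode_h = 3001L,
                            min_final_px = min_wall_px,
                            opening_r = 20L, final_dilate_r = 22L)
  finish_chip(dev2d, nz = d[3], pg_zmax = pg_zmax)
}
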