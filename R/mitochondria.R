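# Mitochondrial assay pipeline (TMRM / MitoTracker live imaging).

#' Segment the mitochondrial assay masks
#'
#' Nucleus mask: raw Hoechst > 100. Cell mask: raw CellMask > 400 (large
#' bright structures) OR difference of Gaussians (100/5 minus 100/30) > 10
#' (small structures). Mitochondria mask: difference of Gaussians (10/1 minus
#' 10/3) > 30, with connected components restricted to 5-500 voxels. Device
#' voxels are removed from every mask. Mitochondrial surfaces and bodies come
#' from 6-connected 3-D erosion, and the skeleton graph from
#' [skeletonize_graph()].
#'
#' @param stack A [channel_stack] for the `mito` assay.
#' @param chip A [chip_masks] object from [segment_chip_mito()].
#' @param nucleus_threshold,cell_global_threshold,cell_local_threshold,mito_threshold
#'   Gray-level thresholds (pipeline fixed values).
#' @param mito_size Inclusive component-size window for mitochondria, voxels.
#' @return List with logical arrays `nucleus`, `cell`, `mito`, `mito_surface`,
#'   `mito_body`, and `mito_graph` (a `skeleton_graph`).
#' @export
segment_mito_assay <- function(stack, chip, nucleus_threshold = 100,
                               cell_global_threshold = 400,
                               cell_local_threshold = 10,
                               mito_threshold = 30, mito_size = c(5, 500)) {
  dev3 <- chip_device_3d(chip)
  hoe <- stack_channel(stack, "hoechst")
  cm <- stack_channel(stack, "cellmask")
  mt <- stack_channel(stack, "mitotracker")

  nucleus <- (hoe > nucleus_threshold) & !dev3
  cell_global <- cm > cell_global_threshold
  cell_local <- difference_of_gaussians(cm, 100, 5, 100, 30) > cell_local_threshold
  cell <- (cell_global | cell_local) & !dev3
  mito_rough <- (difference_of_gaussians(mt, 10, 1, 10, 3) > mito_threshold) & !dev3
  mito <- filter_components_by_size(mito_rough, mito_size[1], mito_size[2])
  es <- erode_with_surface(mito)
  list(nucleus = nucleus, cell = cell, mito = mito,
       mito_surface = es$surface, mito_body = es$eroded,
       mito_graph = skeletonize_graph(mito))
}

#' Extract the mitochondrial feature record of one bioreactor
#'
#' `mito_count` is the number of retained mitochondrial components;
#' `mito_surface_px` doubles as the "perimeter" readout. Per-cell
#' normalisations divide by the cell-mask voxel count and are `NA` when the
#' cell mask is empty.
#'
#' @param masks Output of [segment_mito_assay()].
#' @param meta Named list of bioreactor metadata copied into the record.
#' @return One-row `data.frame`.
#' @export
extract_mito_features <- function(masks, meta = list()) {
  lab <- label_components(masks$mito, 26)
  n <- max(lab)
  sizes <- if (n > 0L) tabulate(lab[lab > 0L], nbins = n) else numeric(0)
  cell_px <- sum(masks$cell)
  g <- masks$mito_graph
  feats <- data.frame(
    mito_count = n,
    mito_px = sum(masks$mito),
    mito_surface_px = sum(masks$mito_surface),
    mito_body_px = sum(masks$mito_body),
    mito_skeleton_px = g$skeleton_px,
    mito_node_count = g$node_count,
    mito_link_count = g$link_count,
    mito_mean_size = if (n > 0L) mean(sizes) else 0,
    nucleus_px = sum(masks$nucleus),
    cell_px = cell_px,
    mito_count_per_cell_px = ratio_or_na(n, cell_px),
    mito_px_per_cell_px = ratio_or_na(sum(masks$mito), cell_px)
  )
  bind_meta(meta, feats)
}
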