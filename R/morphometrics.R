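# Morphometric assay pipeline: Hoechst nuclei (normal vs pyknotic), Tuj1
# neuronal mask, TH dopaminergic mask with fragmentation surfaces, skeleton
# graphs, and the per-bioreactor feature record.

#' Segment nuclei in the morphometric assay
#'
#' Difference of Gaussians (foreground 10/2, background 60/20) on the raw
#' Hoechst channel, thresholded at gray value 10; device-mask voxels are
#' removed and components of at least 200 voxels retained. Nuclei voxels
#' whose size-5 average-filtered raw Hoechst exceeds 400 form the pyknotic
#' mask; the remainder is the normal-nuclei mask.
#'
#' @param hoechst Raw Hoechst volume.
#' @param chip A [chip_masks] object.
#' @param dog_threshold,min_px,pyknotic_threshold Gray-level and size
#'   parameters (defaults are the pipeline's fixed values).
#' @return List of logical arrays `nuclei`, `pyknotic`, `normal`.
#' @export
segment_nuclei_morpho <- function(hoechst, chip, dog_threshold = 10,
                                  min_px = 200, pyknotic_threshold = 400) {
  hoechst <- as_volume(hoechst)
  dog <- difference_of_gaussians(hoechst, 10, 2, 60, 20)
  rough <- dog > dog_threshold & !chip_device_3d(chip)
  nuclei <- filter_components_by_size(rough, min_px)
  avg <- average_filter(hoechst, 5)
  pyknotic <- nuclei & avg > pyknotic_threshold
  list(nuclei = nuclei, pyknotic = pyknotic, normal = nuclei & !pyknotic)
}

#' Segment the neuronal (Tuj1) mask
#'
#' Combines a global threshold (Gaussian low-pass 10/3, gray value 150) with
#' a local one (difference of Gaussians 10/3 minus 20/6, gray value 3);
#' voxels detected by at least one method are kept, device voxels removed,
#' and components under 200 voxels dropped.
#'
#' @param tuj1 Raw Tuj1 volume.
#' @param chip A [chip_masks] object.
#' @param global_threshold,local_threshold,min_px Pipeline parameters.
#' @return Logical neuron mask.
#' @export
segment_neurons <- function(tuj1, chip, global_threshold = 150,
                            local_threshold = 3, min_px = 200) {
  tuj1 <- as_volume(tuj1)
  global_mask <- gaussian_lowpass(tuj1, 10, 3) > global_threshold
  local_mask <- difference_of_gaussians(tuj1, 10, 3, 20, 6) > local_threshold
  combined <- (global_mask | local_mask) & !chip_device_3d(chip)
  filter_components_by_size(combined, min_px)
}

#' Segment the TH (dopaminergic) mask with fragmentation surfaces
#'
#' The TH mask is the Gaussian low-pass (size 10, sigma 1) of the raw TH
#' channel thresholded at gray value 100, minus device voxels. Fragmentation
#' is quantified by 6-connected 3-D erosion: the surface (mask minus its
#' erosion) grows with fragmentation at constant volume. The same erosion is
#' applied to the neuron mask for Tuj1 fragmentation features.
#'
#' @param th Raw TH volume.
#' @param chip A [chip_masks] object.
#' @param neuron_mask Logical mask from [segment_neurons()] (may be `NULL`).
#' @param threshold Gray-level threshold of the smoothed TH channel.
#' @return List with `th_mask`, `th_eroded`, `th_surface`, and (when a neuron
#'   mask is supplied) `neuron_eroded`, `neuron_surface`.
#' @export
segment_th <- function(th, chip, neuron_mask = NULL, threshold = 100) {
  th <- as_volume(th)
  th_mask <- gaussian_lowpass(th, 10, 1) > threshold & !chip_device_3d(chip)
  es <- erode_with_surface(th_mask)
  out <- list(th_mask = th_mask, th_eroded = es$eroded, th_surface = es$surface)
  if (!is.null(neuron_mask)) {
    en <- erode_with_surface(neuron_mask)
    out$neuron_eroded <- en$eroded
    out$neuron_surface <- en$surface
  }
  out
}

#' Skeletonise a mask and extract its branch graph
#'
#' The mask is thinned to a 3-D curve skeleton by sequential removal of
#' simple border points (topology-preserving; curve endpoints are kept).
#' Nodes are skeleton voxels with three or more 26-connected skeleton
#' neighbours, merged when adjacent; links are the maximal skeleton paths
#' between nodes and/or endpoints, counted as the connected components of
#' the skeleton after node-voxel removal. A simple path therefore has zero
#' nodes and one link.
#'
#' @param mask 3-D logical array.
#' @return An object of class `skeleton_graph`: list with `skeleton` (logical
#'   array), `skeleton_px`, `node_count`, `link_count`, `node_labels`
#'   (integer array), and `method` (thinning algorithm identifier).
#' @export
skeletonize_graph <- function(mask) {
  mask <- as_mask(mask)
  skel <- array(thin3d_cpp(as.logical(mask), dim(mask)), dim = dim(mask))
  nb <- array(neighbors26_cpp(as.logical(skel), dim(skel)), dim = dim(skel))
  node_vox <- skel & nb >= 3L
  node_labels <- label_components(node_vox, 26)
  node_count <- max(node_labels)
  link_vox <- skel & !node_vox
  link_count <- max(label_components(link_vox, 26))
  structure(list(skeleton = skel,
                 skeleton_px = sum(skel),
                 node_count = node_count,
                 link_count = link_count,
                 node_labels = node_labels,
                 method = "sequential simple-point thinning (6-subfield)"),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph: %d skeleton px, %d node(s), %d link(s)>\n",
              x$skeleton_px, x$node_count, x$link_count))
  invisible(x)
}

ratio_or_na <- function(num, den) if (isTRUE(den > 0)) num / den else NA_real_

#' Extract the morphometric feature record of one bioreactor
#'
#' Voxel counts are taken over the whole chip minus the device mask (the
#' masks already exclude device voxels). Ratio features with a zero
#' denominator are reported as `NA`.
#'
#' @param nuclei Output of [segment_nuclei_morpho()].
#' @param neuron_mask Output of [segment_neurons()].
#' @param th Output of [segment_th()].
#' @param th_graph A `skeleton_graph` of the TH mask.
#' @param meta Named list of bioreactor metadata copied into the record.
#' @return One-row `data.frame`.
#' @export
extract_morpho_features <- function(nuclei, neuron_mask, th, th_graph,
                                    meta = list()) {
  nuclei_lab <- label_components(nuclei$nuclei, 26)
  pyk_lab <- label_components(nuclei$pyknotic, 26)
  th_count <- max(label_components(th$th_mask, 26))
  tuj1_px <- sum(neuron_mask)
  th_px <- sum(th$th_mask)
  nuclei_px <- sum(nuclei$nuclei)
  nuclei_count <- max(nuclei_lab)
  feats <- data.frame(
    th_px = th_px,
    th_count = th_count,
    th_skeleton_px = th_graph$skeleton_px,
    th_node_count = th_graph$node_count,
    th_link_count = th_graph$link_count,
    th_surface_px = sum(th$th_surface),
    th_body_px = sum(th$th_eroded),
    tuj1_px = tuj1_px,
    neuron_surface_px = if (is.null(th$neuron_surface)) NA_real_ else sum(th$neuron_surface),
    neuron_body_px = if (is.null(th$neuron_eroded)) NA_real_ else sum(th$neuron_eroded),
    th_tuj1_ratio = ratio_or_na(th_px, tuj1_px),
    nuclei_count = nuclei_count,
    nuclei_px = nuclei_px,
    pyknotic_count = max(pyk_lab),
    pyknotic_px = sum(nuclei$pyknotic),
    pyknotic_fraction = ratio_or_na(max(pyk_lab), nuclei_count),
    cell_by_nuclear_volume = ratio_or_na(tuj1_px, nuclei_px)
  )
  bind_meta(meta, feats)
}
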