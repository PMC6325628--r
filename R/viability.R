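# Cell-death assay pipeline (Calcein / ethidium homodimer / cleaved
# caspase-3).

#' Segment the cell-death assay masks
#'
#' Recipes (all gray levels on the raw scale, device voxels always removed):
#' nuclei = difference of Gaussians (10/2 minus 60/20) of Hoechst > 50,
#' components >= 200 voxels; EH = Gaussian low-pass (10/3) > 500; CC3 =
#' Gaussian low-pass (10/3) > 250 minus nuclei, then components >= 20 voxels
#' (exclusion before the size filter); Calcein = low-pass (10/1) > 50 OR
#' difference of Gaussians (20/1 minus 20/5) > 10, minus nuclei; live =
#' Calcein components >= 200 voxels; CC3-live = Calcein AND (NOT nuclei) AND
#' CC3.
#'
#' @param stack A [channel_stack] for the `viability` assay.
#' @param chip A [chip_masks] object from [segment_chip_celldeath()].
#' @param nuclei_threshold,eh_threshold,cc3_threshold,calcein_global_threshold,calcein_local_threshold
#'   Gray-level thresholds (pipeline fixed values).
#' @param nuclei_min_px,cc3_min_px,live_min_px Component-size cut-offs.
#' @return List of logical arrays `nuclei`, `eh`, `cc3`, `calcein`, `live`,
#'   `cc3_live`.
#' @export
segment_viability_assay <- function(stack, chip,
                                    nuclei_threshold = 50, eh_threshold = 500,
                                    cc3_threshold = 250,
                                    calcein_global_threshold = 50,
                                    calcein_local_threshold = 10,
                                    nuclei_min_px = 200, cc3_min_px = 20,
                                    live_min_px = 200) {
  dev3 <- chip_device_3d(chip)
  hoe <- stack_channel(stack, "hoechst")
  cal <- stack_channel(stack, "calcein")
  eh_raw <- stack_channel(stack, "eh")
  cc3_raw <- stack_channel(stack, "cc3")

  nuclei_rough <- (difference_of_gaussians(hoe, 10, 2, 60, 20) > nuclei_threshold) & !dev3
  nuclei <- filter_components_by_size(nuclei_rough, nuclei_min_px)

  eh <- (gaussian_lowpass(eh_raw, 10, 3) > eh_threshold) & !dev3

  cc3 <- (gaussian_lowpass(cc3_raw, 10, 3) > cc3_threshold) & !dev3 & !nuclei
  cc3 <- filter_components_by_size(cc3, cc3_min_px)

  cal_global <- gaussian_lowpass(cal, 10, 1) > calcein_global_threshold
  cal_local <- difference_of_gaussians(cal, 20, 1, 20, 5) > calcein_local_threshold
  calcein <- (cal_global | cal_local) & !dev3 & !nuclei

  live <- filter_components_by_size(calcein, live_min_px)
  cc3_live <- calcein & !nuclei & cc3

  list(nuclei = nuclei, eh = eh, cc3 = cc3, calcein = calcein,
       live = live, cc3_live = cc3_live)
}

#' Extract the viability feature record of one bioreactor
#'
#' The dead fraction, `eh_px / (eh_px + live_px)`, is a convenience summary
#' beyond the core mask counts; ratio features with zero denominators are
#' `NA` (an all-empty bioreactor has no defined dead fraction).
#'
#' @param masks Output of [segment_viability_assay()].
#' @param meta Named list of bioreactor metadata copied into the record.
#' @return One-row `data.frame`.
#' @export
extract_viability_features <- function(masks, meta = list()) {
  count_of <- function(m) max(label_components(m, 26))
  eh_px <- sum(masks$eh)
  live_px <- sum(masks$live)
  feats <- data.frame(
    eh_px = eh_px,
    eh_count = count_of(masks$eh),
    cc3_px = sum(masks$cc3),
    cc3_count = count_of(masks$cc3),
    cc3_live_px = sum(masks$cc3_live),
    cc3_live_count = count_of(masks$cc3_live),
    calcein_px = sum(masks$calcein),
    live_px = live_px,
    live_count = count_of(masks$live),
    nuclei_px = sum(masks$nuclei),
    nuclei_count = count_of(masks$nuclei),
    dead_fraction = ratio_or_na(eh_px, eh_px + live_px),
    cc3_live_fraction = ratio_or_na(sum(masks$cc3_live), live_px)
  )
  bind_meta(meta, feats)
}
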