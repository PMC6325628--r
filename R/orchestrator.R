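# End-to-end orchestration: one bioreactor from raw stack to feature row,
# and a whole study from feature table to statistics and classifier reports.

#' Run the full assay pipeline on one bioreactor stack
#'
#' Chip segmentation, assay segmentation and feature extraction, dispatched
#' on the stack's assay tag. Inputs are never mutated; all parameters used
#' are echoed in the `provenance` element.
#'
#' @param stack A [channel_stack].
#' @param chip Optional precomputed [chip_masks]; segmented from the stack
#'   when `NULL`.
#' @param params Named list of overrides forwarded to the chip and assay
#'   segmentation functions (e.g. `rough_thresholds`, `min_wall_px`).
#' @param meta Metadata for the feature record; defaults to the stack's.
#' @return List with `features` (one-row `data.frame`), `masks`, `chip`,
#'   `provenance`.
#' @export
run_assay <- function(stack, chip = NULL, params = list(), meta = stack$meta) {
  if (!inherits(stack, "channel_stack")) stop("stack must be a channel_stack")
  assay <- stack$assay
  chip_fun <- switch(assay,
                     morpho = segment_chip_morphometric,
                     mito = segment_chip_mito,
                     viability = segment_chip_celldeath)
  chip_args <- params[intersect(names(params), names(formals(chip_fun)))]
  if (is.null(chip))
    chip <- do.call(chip_fun, c(list(stack), chip_args))

  if (assay == "morpho") {
    nuclei <- segment_nuclei_morpho(stack_channel(stack, "hoechst"), chip)
    neuron <- segment_neurons(stack_channel(stack, "tuj1"), chip)
    th <- segment_th(stack_channel(stack, "th"), chip, neuron_mask = neuron)
    graph <- skeletonize_graph(th$th_mask)
    features <- extract_morpho_features(nuclei, neuron, th, graph, meta = meta)
    masks <- c(nuclei, list(neuron = neuron), th)
  } else if (assay == "mito") {
    seg_args <- params[intersect(names(params), names(formals(segment_mito_assay)))]
    masks <- do.call(segment_mito_assay, c(list(stack, chip), seg_args))
    features <- extract_mito_features(masks, meta = meta)
  } else {
    seg_args <- params[intersect(names(params), names(formals(segment_viability_assay)))]
    masks <- do.call(segment_viability_assay, c(list(stack, chip), seg_args))
    features <- extract_viability_features(masks, meta = meta)
  }
  list(features = features, masks = masks, chip = chip,
       provenance = list(assay = assay, params = params,
                         package_version = as.character(utils::packageVersion("phenochip"))))
}

#' Run the statistical and classification plan of a study
#'
#' Aggregated feature rows are analysed per plan entry: group comparisons
#' via [compare_groups()], rescue estimates via [bootstrap_rescue()] (groups
#' selected by metadata filters), and classifier reports via
#' [choose_selection_threshold()] / [evaluate_classifier()].
#'
#' @param table `data.frame` of per-bioreactor feature rows with metadata
#'   columns.
#' @param stats_plan List of entries `list(feature, groups, pairs = NULL,
#'   m = NULL)`.
#' @param rescue_plan List of entries `list(feature, groups = column,
#'   wt, mut, treated, iterations, k)` naming the three group levels.
#' @param classify_plan List of entries `list(label, positive, features =
#'   NULL, select_thresholds = NULL, folds, repeats, c_grid, gamma_grid)`.
#' @param seed Integer seed governing every stochastic step.
#' @return List with `tests` (`data.frame`), `rescue` (list), `classifiers`
#'   (list), `seed`.
#' @export
run_study <- function(table, stats_plan = list(), rescue_plan = list(),
                      classify_plan = list(), seed = 1L) {
  tests <- list()
  for (p in stats_plan) {
    if (!p$groups %in% names(table)) stop(sprintf("plan references missing column '%s'", p$groups))
    tests[[length(tests) + 1L]] <-
      compare_groups(table, p$feature, p$groups,
                     post_hoc_pairs = p$pairs, m_adjust = p$m)
  }
  rescue <- list()
  for (p in rescue_plan) {
    g <- as.character(table[[p$groups]])
    pick <- function(level) table[[p$feature]][g == level]
    wt <- pick(p$wt); mut <- pick(p$mut); tr <- pick(p$treated)
    nm <- sprintf("%s:%s", p$feature, p$treated)
    if (mean(wt) == mean(mut)) {
      warning(sprintf("rescue undefined for %s (equal group means)", nm))
      rescue[[nm]] <- NULL
      next
    }
    rescue[[nm]] <- bootstrap_rescue(wt, mut, tr,
                                     iterations = p$iterations %||% 1e5,
                                     k = p$k %||% 10, seed = seed)
  }
  classifiers <- list()
  for (p in classify_plan) {
    sub <- table
    if (!is.null(p$features)) sub <- sub[c(p$label, p$features)]
    args <- list(labels = p$label, positive = p$positive, seed = seed)
    for (nm in c("folds", "repeats", "c_grid", "gamma_grid", "inner_folds"))
      if (!is.null(p[[nm]])) args[[nm]] <- p[[nm]]
    classifiers[[length(classifiers) + 1L]] <-
      if (is.null(p$select_thresholds))
        do.call(evaluate_classifier, c(list(sub), args))
      else
        do.call(choose_selection_threshold,
                c(list(sub), args, list(candidate_thresholds = p$select_thresholds)))
  }
  list(tests = if (length(tests)) do.call(rbind, tests) else NULL,
       rescue = rescue, classifiers = classifiers, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
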