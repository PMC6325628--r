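Package: phenochip
Title: High-Content 3D Image Analysis for Microfluidic Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of multi-channel 3D fluorescence stacks from
    microfluidic (OrganoPlate-style) neuronal cultures. Segments the chip
    device structures (walls, phase guide, Matrigel and perfusion channels),
    runs three assay-specific segmentation pipelines (dopaminergic
    morphometrics, mitochondrial morphology, calcein/ethidium/caspase cell
    death), extracts per-bioreactor feature tables, and provides the
    downstream statistical layer: interquartile-range outlier removal,
    Mann-Whitney and Kruskal-Wallis tests with Dunn's post hoc comparisons,
    Benjamini-Hochberg adjustment, bootstrap rescue-size estimation, and
    SVM-RBF repeated cross-validated ROC evaluation with correlation-based
    feature selection. Includes a synthetic 3D fixture generator with
    voxel-level ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
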