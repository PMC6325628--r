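---
title: "Automated 3D phenotyping of microfluidic neuronal cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated 3D phenotyping of microfluidic neuronal cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

phenochip analyses multi-channel 3D fluorescence stacks acquired from
neuronal cultures grown in microfluidic culture plates. Each culture chamber
("bioreactor") is one statistical unit: a stack is segmented into device
structures and cellular compartments, a vector of scalar features is
extracted, and groups of bioreactors (genotype, genetic background,
treatment, timepoint) are compared downstream. Three assay types are
supported, each with its own staining scheme and segmentation recipe:

* **morphometric** (fixed immunofluorescence): Hoechst nuclei with a
  pyknotic/normal split, a pan-neuronal Tuj1 mask, and a dopaminergic TH mask
  with fragmentation surfaces and a skeleton branch graph;
* **mitochondrial** (live dyes): nucleus, cell and punctate mitochondria
  masks with surface/body/skeleton morphometrics;
* **cell death**: calcein (live), ethidium homodimer (dead) and cleaved
  caspase-3 (apoptotic) masks, plus derived live and CC3-live masks.

All thresholds in the assay recipes are fixed gray-level values on the raw
camera scale (for example, pyknotic nuclei are nuclei whose 5x5
average-filtered Hoechst signal exceeds 400). The pipelines therefore assume
un-normalised integer-like intensities, and the synthetic fixture generator
renders onto that same scale.

## Image model and conventions

Volumes are `[y, x, z]` arrays; `z = 1` is the bottom-most acquired plane and
x increases rightward. All smoothing filters act plane-wise in 2D, matching
plane-by-plane confocal acquisition; a "Gaussian filter of size N and
standard deviation s" is an N x N truncated kernel normalised to sum 1
(applied separably), with replicate padding at borders and the kernel origin
at element `floor((N+1)/2)` so even sizes are well defined. The difference
of Gaussians (DoG) used for local enhancement is the background blur
subtracted from the foreground blur, with signed values retained.

Connected components use 26-connectivity in 3D (8-connectivity in 2D), the
common default in this field's tooling, and are exposed as a parameter. Size
gates are inclusive: "components with less than N pixels were removed" keeps
a component of exactly N voxels.

Two border conventions deserve explicit statement because they change counts:

* the 6-connected 3D erosion used for surface/body decomposition treats
  out-of-volume neighbours as background, so border voxels always erode;
* the tall rod-shaped (1-pixel-wide) erosions/dilations of the chip
  refinement ignore out-of-image rows (erosion behaves as if padded with
  foreground, dilation with background). Rods taller than the image are
  therefore meaningful: an erosion rod of height 3001 on a 1536-row image
  retains exactly the structures spanning the full image height, which is
  what the rod is for (walls run the whole chamber).

## Chip segmentation

The device mask is computed on size-5 average-filtered maximum projections.
Each assay has its own rough rule (per-channel thresholds for the
morphometric assay; the fixed gray-level band rules for the mitochondrial
and calcein assays, e.g. `10 < TMRM < 30 OR (30 < Hoechst < 200 AND
MitoTracker > 15)`) followed by one shared refinement chain: erosion with a
disk of radius 5, removal of components under 1000 px, dilation with a disk
of radius 20, a vertical rod dilation (height 101; 201 for the cell-death
assay) to close gaps, a vertical rod erosion (height 501; 3001) to delete
everything that is not a full-height wall, and removal of components under
100 000 px. The cell-death recipe appends an opening (disk r20) and a
dilation (disk r22). The refined mask must contain exactly three blocks;
ordered by leftmost column they are wall, phase guide, wall — the middle
block is the phase guide regardless of its size. The Matrigel channel (MC)
is reconstructed in the complement of the device mask from a seed that
extends the phase guide one pixel leftward; the perfusion channel (PC)
likewise rightward. The 2D device mask is projected to all planes and the
phase guide clipped to the lowest eight planes.

The printed mitochondrial rough rule is ambiguous about operator grouping;
the default binds the Hoechst band to the MitoTracker condition (device
walls are TMRM-visible on their own, tissue needs nuclear *and*
mitochondrial signal), and the alternative grouping is selectable via the
`rule` argument. The morphometric rough thresholds are not fixed numbers in
the recipe ("based on fluorescence intensities"); they are configuration
with defaults calibrated once against the synthetic fixtures, and are
echoed in the provenance record of every run.

## Skeleton graphs

Masks are thinned to 3D curve skeletons by sequential removal of simple
border points (a point is simple when its 26-neighbourhood contains exactly
one 26-connected object component and its 18-neighbourhood exactly one
6-connected background component touching the centre); voxels with at most
one object neighbour are endpoints and are never removed, and six
directional subpasses with re-checked sequential deletion keep the result
deterministic and topology-preserving. Nodes are skeleton voxels with three
or more 26-connected skeleton neighbours, merged when adjacent; links are
the connected components of the skeleton after node removal. A straight
path is (0 nodes, 1 link), a Y is (1, 3), an H is (2, 5). One known
limitation: a link joining two *adjacent* node clusters with no intermediate
voxel is not counted; this does not arise on curve-like neurite or
mitochondrial skeletons at realistic voxel sizes.

## The synthetic fixture generator

No raw chip stacks are publicly available, so the generator is a first-class
module that renders what the segmentation recipes assume: two full-height
wall blocks, a phase-guide ridge confined to the lowest eight planes, and MC
and PC corridors; objects are placed only inside the MC with clearance from
the (dilated) device mask. Default geometry is 1536 x 500 x 10 voxels —
tall enough that the 100 000-px wall filter and both rod erosions run at
their standard parameters unchanged, while keeping a single-assay pipeline
run under a minute on one CPU. Default per-channel gray levels clear every
fixed threshold by at least 20% (e.g. pyknotic Hoechst 600 vs 400, EH 1000
vs 500, calcein 400 above the 50..300 chip band), so noise-free recovery of
object counts is exact, and additive Gaussian noise at 5% of the dynamic
range leaves all thresholds more than two noise standard deviations away
from their nearest signal after filtering.

Object placement uses minimum-distance rejection sampling for compact
objects and one row-slot per object for neurite trees (whose span would make
rejection sampling unreliable at realistic densities). Spacings are chosen
so that the DoG halos of neighbouring objects cannot bridge: 28 px for
mitochondrial puncta (tips of two 6-px rods plus blur), 26 px for nuclei,
36 px for cells. Neurite trees have a thick, soma-bright proximal trunk that
tapers into thin faint branches; this mirrors real dendrite tapering and is
what keeps a tree 26-connected through the global-OR-local Tuj1 union (the
DoG dips just outside a bright soma, so an all-faint tree would detach from
its soma). The generator's ground truth records every expected count and the
branch topology (2 nodes, 5 links per default tree) by construction.

What the fixtures deliberately do not emulate: optical point-spread
anisotropy, depth attenuation, uneven illumination, touching/overlapping
cells, and stitching seams. Passing the recovery tests therefore shows that
the recipes are implemented faithfully and are stable to moderate pixel
noise — not that they segment arbitrary real microscopy perfectly.

## Mosaic stitching

Fields are registered pairwise on maximum projections: integer offsets at
the argmax of the normalised cross-correlation over the nominal overlap
strip, searched within +/-25% of the overlap; placement is by translation
only, and overlapping voxels take the maximum of contributing tiles (an
intensity-preserving choice for puncta; distance-weighted feathering is
available). A zero-variance strip (blank corner fields) falls back to the
nominal offset with a warning. Sub-pixel registration is out of scope.

## Statistics

Per feature and group, outliers are removed by the 1 x IQR rule (strictly
outside `[Q1 - IQR, Q3 + IQR]`; quartiles by linear interpolation, type 7,
with the Matlab-like type 5 selectable). Two groups are compared with a
two-sided Mann-Whitney test (exact for small tie-free samples), more with
Kruskal-Wallis plus Dunn's rank-based z tests on declared pairs;
Benjamini-Hochberg adjustment always uses an explicitly declared family
size, never an inferred one.

One property users should know: per-group 1 x IQR trimming ahead of the rank
test is anticonservative. Under a simulated null the trimmed path rejects at
roughly twice the nominal level (about 0.10 at alpha = 0.05 for group sizes
20-65), while the untrimmed path holds the level; the package's tests pin
both behaviours. Trimming remains the default because it is the documented
procedure this pipeline reproduces, and `remove_outliers = FALSE` turns it
off.

The rescue size effect re-expresses a treated group on a scale where the
mutant mean is 0% and the wild-type mean is 100%. It is estimated by
bootstrap: per iteration, k = 10 values are drawn with replacement from each
group and `100 * (mean(treated) - mean(mut)) / (mean(wt) - mean(mut))`
recorded; the estimate is the bootstrap mean with a percentile confidence
interval, seeded and fully reproducible. The reference procedure uses 1e5
iterations; validation runs use 1e4, which changes the Monte-Carlo error of
the summary, not the estimand.

## Classification

Feature selection removes, iteratively, one member of the most correlated
feature pair until all pairwise |Pearson r| fall below a chosen threshold
(candidates 0.75, 0.8, 0.85, 0.9; the candidate with the best mean AUC is
chosen, ties toward the smaller threshold). The member with the larger mean
absolute correlation against the remaining features is dropped, ties broken
by column order. Selection runs once on the full table before
cross-validation — the literal reading of the reference procedure; a
leakage-safe per-fold variant is the recommended alternative when selection
bias matters.

The classifier is an SVM with RBF kernel, evaluated by stratified 5-fold
cross-validation repeated (by default) 200 times. Features are z-scored
with training-fold statistics only. The (C, gamma) grid — 21 log-spaced
cost values in 1e-5..1e5 and 10 gamma values in 1e-3..10 — is searched by
an inner 3-fold cross-validation inside each training split, maximising
AUC, so no test information leaks into model selection. Per repeat,
held-out decision values are pooled into one rank-based AUC (identical to
the trapezoidal ROC integral); the report carries mean +/- sd over repeats
plus accuracy, sensitivity (true-positive rate of the declared positive
class) and specificity from pooled predicted labels. Calibration tests use
reduced grids and 50 repeats: the grid size and repeat count scale runtime,
not the calibration being verified, and both are declared arguments.

The chance-level check averages the pooled-CV AUC over five independent
null datasets of 100 samples per class. A single small null dataset is not
a usable check: its cross-validated AUC estimates that dataset's chance
separability, which has a standard deviation of ~0.09 at 20 samples per
class, so any narrow band around 0.5 would be a coin flip.

## Numerical and degenerate-input choices

Constant features correlate with nothing and are treated as |r| = 0 with a
warning; ratio features with zero denominators are reported missing rather
than infinite; an empty mask skeletonises to zero counts; reconstruction
ignores seed voxels outside the limit mask; NCC ties resolve toward the
smaller shift; all stochastic components (generator, bootstrap, fold
assignment) are governed by explicit integer seeds and are bit-identical
across runs. Validation problem sizes — one fixture per assay per noise
level, 1e4 bootstrap iterations, 50 CV repeats, 1000 null features — were
chosen to give each check clear statistical resolution at desk-scale
runtimes and are stated alongside the checks.

## Known limitations

Chip orientation is assumed upright (vertical walls, MC left of the phase
guide); multi-chip images and rotation correction are out of scope, as are
deconvolution, flat-field correction and sub-pixel stitching. Feature counts
are reported in voxels; physical-unit conversion is metadata-driven and
optional. The pyknotic/normal split and all other fixed thresholds assume
raw, un-normalised gray levels — data on other scales must be rescaled
before segmentation.
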