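fixture_morpho <- function(seed = 5) {
  fx <- generate_chip_stack(small_spec(), "morpho", seed = seed)
  chip <- do.call(segment_chip_morphometric, c(list(fx$stack), small_chip_params))
  list(fx = fx, chip = chip)
}

test_that("nuclei segmentation recovers counts and the pyknotic partition", {
  got <- fixture_morpho()
  nuc <- segment_nuclei_morpho(got$fx$stack$channels$hoechst, got$chip)
  expect_equal(max(label_components(nuc$nuclei)), got$fx$truth$counts$nuclei)
  expect_equal(max(label_components(nuc$pyknotic)), got$fx$truth$counts$pyknotic)
  # pyknotic and normal partition the nuclei mask
  expect_false(any(nuc$pyknotic & nuc$normal))
  expect_equal(nuc$pyknotic | nuc$normal, nuc$nuclei)
  # no nucleus voxel inside the device
  expect_false(any(nuc$nuclei & chip_device_3d(got$chip)))
})

test_that("sub-threshold nuclei and device-covered nuclei are excluded", {
  got <- fixture_morpho(seed = 9)
  hoechst <- got$fx$stack$channels$hoechst
  lay <- got$fx$truth$layout
  # a tiny blob whose segmented component stays below 200 voxels
  hoechst[200:202, lay$mc[1] + 70 + 0:2, 5] <- 300
  # a normal-size nucleus entirely inside a wall block
  wall_col <- lay$wall1[1] + 20
  hoechst[300 + (-4:4), wall_col + (-4:4), 4:6] <- 300
  nuc <- segment_nuclei_morpho(hoechst, got$chip)
  expect_equal(max(label_components(nuc$nuclei)), got$fx$truth$counts$nuclei)
})

test_that("neuron segmentation unions global somata with local faint neurites", {
  got <- fixture_morpho()
  tuj1 <- got$fx$stack$channels$tuj1
  mask <- segment_neurons(tuj1, got$chip)
  expect_equal(max(label_components(mask)), got$fx$truth$counts$neurons)

  # constant dim image: DoG == 0 and low-pass < 150 -> empty
  dim_const <- array(50, dim = dim(tuj1))
  expect_equal(sum(segment_neurons(dim_const, got$chip)), 0)

  # a 2-voxel-wide faint neurite alone (never above the global threshold)
  faint <- array(0, dim = dim(tuj1))
  lay <- got$fx$truth$layout
  faint[100:260, lay$mc[1] + 70 + 0:1, 5] <- 120
  m2 <- segment_neurons(faint, got$chip)
  expect_gt(sum(m2), 200)
  expect_lt(max(gaussian_lowpass(faint, 10, 3)), 150)  # really local-only
})

test_that("TH segmentation produces an eroded body plus surface partition", {
  got <- fixture_morpho()
  th <- segment_th(got$fx$stack$channels$th, got$chip)
  expect_equal(max(label_components(th$th_mask)), got$fx$truth$counts$th)
  expect_equal(th$th_eroded | th$th_surface, th$th_mask)
  expect_false(any(th$th_eroded & th$th_surface))

  empty <- array(0, dim = dim(got$fx$stack$channels$th))
  th0 <- segment_th(empty, got$chip)
  expect_equal(sum(th0$th_mask) + sum(th0$th_eroded) + sum(th0$th_surface), 0)
})

test_that("fragmentation increases surface count at matched volume", {
  # solid rod vs the same voxels cut into 1-voxel-thick slabs
  solid <- array(FALSE, dim = c(40, 12, 8)); solid[5:34, 3:8, 2:7] <- TRUE
  pieces <- array(FALSE, dim = dim(solid))
  for (y in seq(5, 33, by = 2)) pieces[y, 3:8, 2:7] <- TRUE  # 15 slabs
  es_solid <- erode_with_surface(solid)
  es_piece <- erode_with_surface(pieces)
  expect_gt(sum(es_piece$surface) / sum(pieces),
            sum(es_solid$surface) / sum(solid))
  expect_equal(sum(es_piece$eroded), 0)   # fully fragmented: no body voxels
})

test_that("skeleton graphs match hand enumeration on canonical shapes", {
  g <- skeletonize_graph(line_mask(20))
  expect_equal(g$skeleton_px, 20)
  expect_equal(g$node_count, 0)
  expect_equal(g$link_count, 1)

  y <- array(FALSE, dim = c(21, 21, 3))
  y[1:10, 11, 2] <- TRUE
  for (i in 1:7) { y[10 + i, 11 - i, 2] <- TRUE; y[10 + i, 11 + i, 2] <- TRUE }
  gy <- skeletonize_graph(y)
  expect_equal(gy$node_count, 1)
  expect_equal(gy$link_count, 3)

  two <- array(FALSE, dim = c(20, 9, 3))
  two[2:15, 3, 2] <- TRUE; two[2:15, 7, 2] <- TRUE
  gt <- skeletonize_graph(two)
  expect_equal(gt$node_count, 0)
  expect_equal(gt$link_count, 2)

  g0 <- skeletonize_graph(array(FALSE, dim = c(4, 4, 4)))
  expect_equal(g0$skeleton_px + g0$node_count + g0$link_count, 0)
})

test_that("thinning reduces a thick tube to a single-link centreline", {
  tube <- array(FALSE, dim = c(40, 11, 7)); tube[4:36, 4:7, 3:5] <- TRUE
  g <- skeletonize_graph(tube)
  expect_equal(g$link_count, 1)
  expect_equal(g$node_count, 0)
  expect_lt(g$skeleton_px, sum(tube) / 4)
  # per-component link lower bound on fixture-like skeletons
  expect_gte(g$link_count, max(1, g$node_count))
})

test_that("morphometric feature extraction does exact bookkeeping", {
  d <- c(30, 30, 6)
  nuclei <- array(FALSE, dim = d); nuclei[3:7, 3:7, 2:4] <- TRUE     # 75 vox
  pyk <- array(FALSE, dim = d); pyk[3:5, 3:7, 2:4] <- TRUE           # 45 vox
  nuc <- list(nuclei = nuclei, pyknotic = pyk, normal = nuclei & !pyk)
  neuron <- array(FALSE, dim = d); neuron[12:21, 5:14, 2:4] <- TRUE  # 300 vox
  th_mask <- array(FALSE, dim = d); th_mask[24:28, 10:14, 3] <- TRUE # 25 vox
  es <- erode_with_surface(th_mask)
  th <- list(th_mask = th_mask, th_eroded = es$eroded, th_surface = es$surface)
  graph <- skeletonize_graph(th_mask)
  f <- extract_morpho_features(nuc, neuron, th, graph,
                               meta = list(bioreactor_id = "B1", genotype = "WT"))
  expect_equal(f$nuclei_px, 75)
  expect_equal(f$pyknotic_px, 45)
  expect_equal(f$nuclei_count, 1)
  expect_equal(f$tuj1_px, 300)
  expect_equal(f$th_px, 25)
  expect_equal(f$th_tuj1_ratio, 25 / 300)
  expect_equal(f$cell_by_nuclear_volume, 300 / 75)
  expect_equal(f$th_surface_px + f$th_body_px, 25)
  expect_equal(f$genotype, "WT")

  # stacking two disjoint copies doubles every count feature
  dbl <- function(m) { out <- array(FALSE, dim = d + c(40, 0, 0))
    out[1:30, , ] <- m; out[31:60, , ][m] <- TRUE; out }
  nuc2 <- list(nuclei = dbl(nuclei), pyknotic = dbl(pyk),
               normal = dbl(nuclei & !pyk))
  th2m <- dbl(th_mask); es2 <- erode_with_surface(th2m)
  th2 <- list(th_mask = th2m, th_eroded = es2$eroded, th_surface = es2$surface)
  f2 <- extract_morpho_features(nuc2, dbl(neuron), th2, skeletonize_graph(th2m))
  for (col in c("nuclei_px", "pyknotic_px", "tuj1_px", "th_px",
                "th_surface_px", "nuclei_count", "th_skeleton_px"))
    expect_equal(f2[[col]], 2 * f[[col]], info = col)

  # empty TH: zero counts, ratio features missing
  th0m <- array(FALSE, dim = d); es0 <- erode_with_surface(th0m)
  th0 <- list(th_mask = th0m, th_eroded = es0$eroded, th_surface = es0$surface)
  f0 <- extract_morpho_features(nuc, array(FALSE, dim = d), th0,
                                skeletonize_graph(th0m))
  expect_equal(f0$th_px, 0)
  expect_true(is.na(f0$th_tuj1_ratio))
})
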