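# Chip segmentation on scaled-down fixtures (geometry and wall-size cut-off
# shrunk together so the refinement chain runs unchanged).

chip_of <- function(assay, seed = 5, noise = 0) {
  fx <- generate_chip_stack(small_spec(noise_frac = noise), assay, seed = seed)
  fun <- switch(assay, morpho = segment_chip_morphometric,
                mito = segment_chip_mito, viability = segment_chip_celldeath)
  list(fx = fx, chip = do.call(fun, c(list(fx$stack), small_chip_params)))
}

test_that("morphometric chip segmentation recovers walls, phase guide, MC and PC", {
  got <- chip_of("morpho")
  chip <- got$chip; lay <- got$fx$truth$layout
  # all true wall and phase-guide columns are inside the device mask
  expect_true(all(chip$device[, lay$wall1[1]:lay$wall1[2]]))
  expect_true(all(chip$device[, lay$wall2[1]:lay$wall2[2]]))
  expect_true(all(chip$phaseguide[, lay$pg[1]:lay$pg[2]]))
  # channels flank the phase guide on the correct sides
  expect_true(all(which(colSums(chip$mc) > 0) < lay$pg[1]))
  expect_true(all(which(colSums(chip$pc) > 0) > lay$pg[2]))
  expect_false(any(chip$mc & chip$pc))
  # device + channels jointly cover (almost) the whole chip footprint
  foot <- chip$device | chip$mc | chip$pc
  cols <- lay$wall1[1]:lay$wall2[2]
  expect_gte(mean(foot[, cols]), 0.99)
})

test_that("phase-guide voxels are confined to the lowest eight planes", {
  got <- chip_of("morpho")
  dev3 <- chip_device_3d(got$chip)
  pg <- got$chip$phaseguide
  for (z in seq_len(dim(dev3)[3])) {
    plane_pg <- dev3[, , z] & pg
    if (z <= got$chip$pg_zmax) expect_true(all(plane_pg == pg))
    else expect_false(any(plane_pg))
  }
})

test_that("a blank stack raises a chip-not-found error", {
  blank <- channel_stack(list(hoechst = array(0, c(60, 60, 2)),
                              tuj1 = array(0, c(60, 60, 2)),
                              th = array(0, c(60, 60, 2)),
                              marker647 = array(0, c(60, 60, 2))), "morpho")
  expect_error(segment_chip_morphometric(blank), "chip not found")
})

test_that("small spurious blobs are removed by the component filter", {
  fx <- generate_chip_stack(small_spec(), "morpho", seed = 6)
  st <- fx$stack
  # paint a bright blob (~900 px after erosion it is far below 1000) in the MC
  lay <- fx$truth$layout
  st$channels$hoechst[180:209, (lay$mc[1] + 60):(lay$mc[1] + 89), ] <- 500
  chip <- do.call(segment_chip_morphometric, c(list(st), small_chip_params))
  expect_false(any(chip$device[180:209, (lay$mc[1] + 60):(lay$mc[1] + 89)]))
})

test_that("phase-guide detection picks the middle block by position, never size", {
  m <- matrix(FALSE, 40, 100)
  m[, 10:12] <- TRUE; m[5:10, 50:52] <- TRUE; m[, 90:92] <- TRUE  # middle smallest
  pg <- detect_phaseguide(m)
  expect_true(all(pg[5:10, 50:52]))
  expect_equal(sum(pg), sum(m[5:10, 50:52]))

  two <- matrix(FALSE, 40, 100); two[, 10:12] <- TRUE; two[, 90:92] <- TRUE
  expect_error(detect_phaseguide(two), "phase-guide ambiguity.*2")
})

test_that("channel derivation reconstructs disjoint MC left and PC right", {
  set.seed(12)
  for (i in 1:20) {
    w <- sort(sample(5:90, 3))
    while (min(diff(w)) < 12) w <- sort(sample(5:90, 3))
    dev <- matrix(FALSE, 30, 100)
    for (x in w) dev[, x:(x + 3)] <- TRUE
    pg <- detect_phaseguide(dev)
    ch <- derive_channels(pg, dev)
    expect_false(any(ch$mc & ch$pc))
    expect_false(any(ch$mc & dev) || any(ch$pc & dev))
    expect_true(all(which(colSums(ch$mc) > 0) < w[2]))
    expect_true(all(which(colSums(ch$pc) > 0) > w[2]))
  }

  # phase guide flush against a wall: that side reconstructs empty, warning
  dev <- matrix(FALSE, 20, 30)
  dev[, 1:13] <- TRUE                      # wall merged into the guide's left
  pg <- matrix(FALSE, 20, 30); pg[, 11:13] <- TRUE
  expect_warning(ch <- derive_channels(pg, dev), "empty")
  expect_equal(sum(ch$mc), 0)
  expect_gt(sum(ch$pc), 0)
})

test_that("the mito chip rule follows the stated operator precedence", {
  base <- array(0, dim = c(150, 120, 2))
  mk <- function(tmrm, hoe, mito) {
    channel_stack(list(hoechst = base + hoe, mitotracker = base + mito,
                       tmrm = base + tmrm, cellmask = base), "mito")
  }
  rough_of <- function(stack, rule = "tmrm_or_nuclear_and_mito") {
    tm <- max_project(average_filter(stack$channels$tmrm, 5))
    ho <- max_project(average_filter(stack$channels$hoechst, 5))
    mi <- max_project(average_filter(stack$channels$mitotracker, 5))
    if (rule == "tmrm_or_nuclear_and_mito")
      (tm > 10 & tm < 30) | ((ho > 30 & ho < 200) & (mi > 15))
    else ((tm > 10 & tm < 30) | (ho > 30 & ho < 200)) & (mi > 15)
  }
  # constant stacks make the average-filtered projection equal the raw level,
  # so each rule clause can be probed directly
  expect_true(all(rough_of(mk(20, 0, 0))))          # TMRM range alone
  expect_false(any(rough_of(mk(0, 100, 10))))       # Hoechst alone: AND fails
  expect_true(all(rough_of(mk(5, 100, 16))))        # Hoechst AND mito
  expect_false(any(rough_of(mk(20, 0, 0), "range_or_and_mito")))  # grouping flag
})

test_that("mito and cell-death chip recipes recover the device on fixtures", {
  for (assay in c("mito", "viability")) {
    got <- chip_of(assay)
    chip <- got$chip; lay <- got$fx$truth$layout
    expect_true(all(chip$device[, lay$wall1[1]:lay$wall1[2]]))
    expect_true(all(chip$device[, lay$wall2[1]:lay$wall2[2]]))
    expect_true(all(chip$phaseguide[, lay$pg[1]:lay$pg[2]]))
    expect_false(any(chip$mc & chip$pc))
  }
  blank <- channel_stack(list(hoechst = array(0, c(60, 60, 2)),
                              calcein = array(0, c(60, 60, 2)),
                              eh = array(0, c(60, 60, 2)),
                              cc3 = array(0, c(60, 60, 2))), "viability")
  expect_error(segment_chip_celldeath(blank), "chip not found")
})

test_that("chip segmentation is deterministic", {
  fx <- generate_chip_stack(small_spec(), "morpho", seed = 17)
  c1 <- do.call(segment_chip_morphometric, c(list(fx$stack), small_chip_params))
  c2 <- do.call(segment_chip_morphometric, c(list(fx$stack), small_chip_params))
  expect_identical(c1$device, c2$device)
  expect_identical(c1$mc, c2$mc)
})
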