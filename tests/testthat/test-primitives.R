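test_that("gaussian low-pass preserves constants and matches the kernel oracle", {
  const <- array(7.5, dim = c(15, 15, 2))
  out <- gaussian_lowpass(const, 10, 2)
  expect_equal(out, const)

  # impulse response equals direct 2-D kernel correlation (even + odd sizes)
  set.seed(11)
  vol <- array(0, dim = c(21, 21, 1)); vol[11, 11, 1] <- 1
  for (sz in c(10, 11)) {
    got <- gaussian_lowpass(vol, sz, 2)
    want <- naive_filter_vol(vol, gaussian_kernel1d(sz, 2))
    expect_equal(got, want, tolerance = 1e-12)
  }

  # plane-wise independence: identical planes filter identically
  plane <- matrix(runif(15 * 15) * 100, 15, 15)
  two <- array(c(plane, plane), dim = c(15, 15, 2))
  out2 <- gaussian_lowpass(two, 10, 3)
  expect_equal(out2[, , 1], out2[, , 2])

  expect_error(gaussian_lowpass(const, 10, 0), "sigma")
  expect_error(gaussian_lowpass(const, 0, 2), "size")
})

test_that("difference of Gaussians is zero on constants, linear, and matches the oracle", {
  const <- array(3, dim = c(12, 12, 2))
  expect_equal(difference_of_gaussians(const, 5, 1, 9, 3),
               array(0, dim = dim(const)), tolerance = 1e-12)

  set.seed(4)
  vol <- array(runif(12 * 12 * 2) * 50, dim = c(12, 12, 2))
  d1 <- difference_of_gaussians(vol, 5, 1, 9, 3)
  d2 <- difference_of_gaussians(vol * 3, 5, 1, 9, 3)
  expect_equal(d2, 3 * d1, tolerance = 1e-9)

  want <- naive_filter_vol(vol, gaussian_kernel1d(5, 1)) -
    naive_filter_vol(vol, gaussian_kernel1d(9, 3))
  expect_equal(d1, want, tolerance = 1e-10)

  # impulse: positive centre, negative ring
  imp <- array(0, dim = c(15, 15, 1)); imp[8, 8, 1] <- 1
  resp <- difference_of_gaussians(imp, 5, 1, 9, 3)
  expect_gt(resp[8, 8, 1], 0)
  expect_lt(resp[8, 4, 1], 0)

  expect_error(difference_of_gaussians(const, 5, 3, 9, 1), "sigma")
})

test_that("average filter preserves constants, is identity at side 1, and spreads an impulse", {
  const <- array(2.5, dim = c(9, 9, 2))
  expect_equal(average_filter(const, 5), const)
  set.seed(8)
  vol <- array(runif(9 * 9 * 2), dim = c(9, 9, 2))
  expect_equal(average_filter(vol, 1), vol)

  imp <- array(0, dim = c(5, 5, 1)); imp[3, 3, 1] <- 25
  expect_equal(average_filter(imp, 5)[, , 1], matrix(1, 5, 5), tolerance = 1e-12)
})

test_that("maximum projection matches the element-wise oracle", {
  one <- array(runif(6 * 7), dim = c(6, 7, 1))
  expect_equal(max_project(one), one[, , 1])

  lower <- array(1, dim = c(4, 4, 2)); lower[, , 2] <- 5
  expect_equal(max_project(lower), matrix(5, 4, 4))

  set.seed(21)
  vol <- array(runif(8 * 9 * 4), dim = c(8, 9, 4))
  expect_equal(max_project(vol), naive_max_project(vol))
})

test_that("component size filter keeps [min, max] inclusive and matches BFS labelling", {
  m <- array(FALSE, dim = c(20, 20, 2))
  m[2:5, 2, 1] <- TRUE            # 4 voxels
  m[10:14, 10, 1] <- TRUE         # 5 voxels
  out <- filter_components_by_size(m, 5, 500)
  expect_false(any(out[2:5, 2, 1]))
  expect_true(all(out[10:14, 10, 1]))

  empty <- array(FALSE, dim = c(5, 5, 2))
  expect_equal(filter_components_by_size(empty, 1), empty)

  expect_error(filter_components_by_size(m, 10, 5), "max_px")

  set.seed(3)
  for (i in 1:5) {
    msk <- random_mask(c(12, 10, 4), p = 0.25)
    expect_equal(filter_components_by_size(msk, 3, 20),
                 naive_size_filter(msk, 3, 20))
  }
})

test_that("6-connected erosion partitions the mask into body and surface", {
  cube <- array(FALSE, dim = c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  es <- erode_with_surface(cube)
  expect_equal(sum(es$eroded), 1)
  expect_true(es$eroded[3, 3, 3])
  expect_equal(sum(es$surface), 26)

  sheet <- array(FALSE, dim = c(6, 6, 3)); sheet[2:5, 2:5, 2] <- TRUE
  es2 <- erode_with_surface(sheet)
  expect_equal(sum(es2$eroded), 0)
  expect_equal(es2$surface, sheet)

  empty <- array(FALSE, dim = c(4, 4, 4))
  es3 <- erode_with_surface(empty)
  expect_equal(sum(es3$eroded) + sum(es3$surface), 0)

  set.seed(5)
  for (i in 1:5) {
    msk <- random_mask(c(10, 9, 5), p = 0.5)
    es <- erode_with_surface(msk)
    expect_equal(es$eroded, naive_erode6(msk))
    expect_false(any(es$eroded & es$surface))
    expect_equal(es$eroded | es$surface, msk)
  }
})

test_that("reconstruction returns seed-touched components and is idempotent", {
  limit <- array(FALSE, dim = c(10, 10, 2))
  limit[2:4, 2:4, 1] <- TRUE
  limit[7:9, 7:9, 1] <- TRUE
  seed <- array(FALSE, dim = dim(limit)); seed[3, 3, 1] <- TRUE
  got <- reconstruct_mask(seed, limit)
  expect_true(all(got[2:4, 2:4, 1]))
  expect_false(any(got[7:9, 7:9, 1]))

  none <- array(FALSE, dim = dim(limit)); none[6, 6, 2] <- TRUE
  expect_equal(sum(reconstruct_mask(none, limit)), 0)
  expect_equal(reconstruct_mask(limit, limit), limit)

  set.seed(9)
  for (i in 1:5) {
    lim <- random_mask(c(10, 8, 3), p = 0.3)
    sd_ <- random_mask(c(10, 8, 3), p = 0.1)
    r1 <- reconstruct_mask(sd_, lim)
    expect_equal(r1, naive_reconstruct(sd_, lim))
    expect_equal(reconstruct_mask(r1, lim), r1)     # idempotence
  }
})

test_that("mosaic stitching recovers known integer shifts", {
  one <- array(runif(20 * 20 * 2), dim = c(20, 20, 2))
  st1 <- stitch_mosaic(list(one), 1, 1, overlap = 5)
  expect_equal(st1$volume, one)

  set.seed(14)
  big <- array(runif(130 * 150 * 2) * 100, dim = c(130, 150, 2))
  ov <- 20
  a <- big[1:100, 1:60, , drop = FALSE]
  for (shift in c(0L, 3L, -2L)) {
    x0 <- 60 - ov + 1 + shift
    b <- big[1:100, x0:(x0 + 59), , drop = FALSE]
    st <- stitch_mosaic(list(a, b), 1, 2, overlap = ov)
    expect_equal(st$positions[2, ], c(0L, 60L - ov + shift))
  }
  # vertical pair with a row shift
  a2 <- big[1:60, 1:100, , drop = FALSE]
  b2 <- big[(60 - ov + 1 - 2):(60 - ov + 60 - 2), 1:100, , drop = FALSE]
  st2 <- stitch_mosaic(list(a2, b2), 2, 1, overlap = ov)
  expect_equal(st2$positions[2, ], c(60L - ov - 2L, 0L))

  # zero-variance strips fall back to the nominal offset with a warning
  flat <- array(1, dim = c(30, 30, 1))
  expect_warning(stf <- stitch_mosaic(list(flat, flat), 1, 2, overlap = 6),
                 "zero-variance")
  expect_equal(stf$positions[2, ], c(0L, 24L))
  expect_true(stf$fallback[2])
})

test_that("stitching stays within one pixel under moderate noise", {
  set.seed(31)
  big <- array(runif(120 * 150) * 100, dim = c(120, 150, 1))
  ov <- 20
  a <- big[1:100, 1:60, , drop = FALSE]
  b <- big[1:100, 44:103, , drop = FALSE]   # nominal 41, shift +3
  nz <- function(v) pmax(v + array(rnorm(length(v), 0, 10), dim = dim(v)), 0)
  st <- stitch_mosaic(list(nz(a), nz(b)), 1, 2, overlap = ov)
  expect_lte(max(abs(st$positions[2, ] - c(0, 43))), 1)
})

test_that("volume containers validate their invariants", {
  expect_error(as_volume(array(-1, dim = c(2, 2, 2))), ">= 0")
  expect_error(as_volume(1:5), "3-D")
  expect_error(channel_stack(list(array(1, c(2, 2, 2))), "morpho"), "named")
  expect_error(channel_stack(list(a = array(1, c(2, 2, 2)),
                                  b = array(1, c(3, 2, 2))), "morpho"),
               "same shape")

  v <- array(runif(6 * 5 * 3) * 1000, dim = c(6, 5, 3))
  f <- tempfile(fileext = ".tif")
  write_volume_tiff(v, f, scale = 2000)
  v2 <- read_volume_tiff(f, scale = 2000)
  expect_lt(max(abs(v - v2)), 2000 / 65535 + 1e-9)  # 16-bit quantisation
})
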