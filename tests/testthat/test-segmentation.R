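test_that("find_suvmax locates the maximum and breaks ties by first linear index", {
  img <- toy_center_image()
  peak <- find_suvmax(img)
  expect_equal(peak$suvmax, 10)
  expect_equal(peak$index, c(1, 1, 1))   # 0-based center of the 3^3 grid
  # single-voxel VOI
  v <- voi_box(c(0, 0, 0), c(0, 0, 0))
  one <- find_suvmax(img, v)
  expect_equal(one$suvmax, 1)
  expect_equal(one$index, c(0, 0, 0))
  # tie: two voxels at the max; the smaller linear index wins
  a <- array(1, c(4, 4, 4)); a[3, 1, 1] <- 9; a[1, 1, 3] <- 9
  tied <- suv_image(a, volume_grid(c(4, 4, 4)))
  expect_equal(find_suvmax(tied)$index, c(2, 0, 0))
})

test_that("the hand-enumerated 3x3x3 sub-volume comes out exactly", {
  img <- toy_center_image()
  sv <- delineate(img, voi_whole_image(img), 0.5)
  expect_equal(sv$n_voxels, 7L)
  expect_equal(sv$mtv_cc, 7 * 0.064)
  expect_equal(sv$suv_mean, (10 + 6 * 6) / 7)
  # fraction 1.0 keeps only the SUVmax voxel
  top <- delineate(img, voi_whole_image(img), 1.0)
  expect_equal(top$n_voxels, 1L)
  expect_equal(top$mtv_cc, 0.064)
})

test_that("TLG follows the MTV x SUVmean definition", {
  img <- toy_center_image()
  m40 <- delineate(img, voi_whole_image(img), 0.40)
  expect_equal(tlg(img, m40), m40$mtv_cc * m40$suv_mean)
  expect_equal(m40$tlg, m40$mtv_cc * m40$suv_mean)
  # the 0.5-fraction toy example: 0.448 cc x 46/7
  m50 <- delineate(img, voi_whole_image(img), 0.50)
  expect_error(tlg(img, m50), "40%")
  # uniform 10-voxel lesion at SUV 10: TLG = 0.64 x 10
  a <- array(0.1, c(5, 5, 5)); a[1:10] <- 10
  u <- suv_image(a, volume_grid(c(5, 5, 5)))
  u40 <- delineate(u, voi_whole_image(u), 0.40)
  expect_equal(tlg(u, u40), 0.64 * 10)
})

test_that("delineation matches an independent flood-fill oracle on random images", {
  for (s in 1:50) {
    img <- rand_pet(c(16, 16, 16), seed = 600 + s)
    sv <- delineate(img, voi_whole_image(img), 0.7)
    peak <- find_suvmax(img)
    cand <- img$values >= 0.7 * peak$suvmax
    oracle <- oracle_flood_26(cand, peak$index + 1L)
    expect_identical(sv$mask$membership, oracle)
  }
})

test_that("the threshold series is nested with non-increasing volumes", {
  ph <- quiet_phantom(group = "LRRD", seed = 61)
  voi <- as_voi(derive_region(ph$baseline_pet, 0.5, 0), margin_mm = 16)
  ser <- delineate_series(ph$baseline_pet, voi)
  expect_named(ser, sprintf("I%d", seq(30, 90, 10)))
  expect_length(ser, 7)
  vols <- vapply(ser, function(s) s$mtv_cc, numeric(1))
  expect_true(all(diff(vols) <= 0))
  for (i in 1:6) {
    hi <- ser[[i + 1]]$mask$membership
    lo <- ser[[i]]$mask$membership
    expect_true(all(lo[hi]))   # higher-threshold mask is a subset
  }
  # SUVmean lies in [fraction x SUVmax, SUVmax]
  for (s in ser) {
    expect_gte(s$suv_mean, s$fraction * s$suvmax)
    expect_lte(s$suv_mean, s$suvmax)
  }
})

test_that("MTV scales with the voxel volume for the same index set", {
  img4 <- toy_center_image(spacing = c(4, 4, 4))
  img8 <- toy_center_image(spacing = c(8, 8, 8))
  sv4 <- delineate(img4, voi_whole_image(img4), 0.5)
  sv8 <- delineate(img8, voi_whole_image(img8), 0.5)
  expect_equal(sv8$mtv_cc, 8 * sv4$mtv_cc)
})

test_that("precondition violations error", {
  img <- toy_center_image()
  expect_error(delineate(img, voi_whole_image(img), 0), "fraction")
  expect_error(delineate(img, voi_whole_image(img), 1.2), "fraction")
  expect_error(voi_box(c(0, 0, 0), c(-1, 0, 0)), ">=")
  far <- voi_box(c(500, 500, 500), c(600, 600, 600))
  expect_error(find_suvmax(img, far), "no voxel")
})
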