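test_that("a transform composed with its inverse is the identity", {
  set.seed(3)
  for (i in 1:20) {
    tf <- rigid_transform(runif(3, -20, 20), runif(3, -10, 10),
                          center = runif(3, -50, 50))
    id <- compose_transforms(tf, invert_transform(tf))
    expect_true(is_identity_transform(id, tol_mm = 1e-9, tol_deg = 1e-9))
  }
})

test_that("rigid transforms preserve inter-point distances", {
  set.seed(4)
  pts <- matrix(runif(30, -100, 100), ncol = 3)
  tf <- rigid_transform(c(5, -3, 7), c(4, -2, 6), center = c(10, 0, 0))
  out <- transform_points(tf, pts)
  expect_equal(as.vector(dist(out)), as.vector(dist(pts)), tolerance = 1e-10)
  # pure translation moves every point by exactly t
  tt <- rigid_transform(c(1, 2, 3))
  expect_equal(transform_points(tt, pts), sweep(pts, 2, c(1, 2, 3), "+"))
})

test_that("Euler Z-Y-X angles survive a matrix round-trip", {
  set.seed(5)
  for (i in 1:20) {
    tf <- rigid_transform(runif(3, -10, 10), runif(3, -80, 80),
                          center = runif(3, -20, 20))
    back <- petsubvol:::matrix_to_transform(petsubvol:::transform_matrix(tf),
                                            tf$center)
    expect_equal(back$rotation, tf$rotation, tolerance = 1e-9)
    expect_equal(back$translation, tf$translation, tolerance = 1e-9)
  }
})

test_that("transform JSON serialization round-trips", {
  tf <- rigid_transform(c(6, -4, 8), c(3, 0, -2), center = c(1, 2, 3))
  f <- withr::local_tempfile(fileext = ".json")
  write_transform(tf, f)
  back <- read_transform(f)
  expect_equal(back$translation, tf$translation)
  expect_equal(back$rotation, tf$rotation)
  expect_equal(back$center, tf$center)
})

test_that("apply_rigid with the identity on the same grid is a no-op", {
  img <- rand_pet(c(6, 7, 8), seed = 6)
  out <- apply_rigid(img, rigid_transform(), img$grid)
  expect_equal(out$values, img$values, tolerance = 1e-12)
})

test_that("translation by one voxel with nearest interpolation shifts with zero fill", {
  img <- rand_pet(c(6, 6, 6), seed = 7)
  sp <- img$grid$spacing[1]
  out <- apply_rigid(img, rigid_transform(translation = c(sp, 0, 0)),
                     img$grid, interpolation = "nearest")
  expect_equal(out$values[1:5, , ], img$values[2:6, , ])
  expect_true(all(out$values[6, , ] == 0))
})

test_that("trilinear resampling is bounded and exact on constants", {
  g <- volume_grid(c(10, 10, 10), spacing = c(4, 4, 4), origin = c(-18, -18, -18))
  const <- suv_image(array(7, c(10, 10, 10)), g)
  tf <- rigid_transform(c(1.3, -0.7, 2.1), c(2, -1, 3),
                        center = c(0, 0, 0))
  out <- apply_rigid(const, tf, g)
  inner <- out$values[3:8, 3:8, 3:8]   # interior, away from the zero fill
  expect_equal(inner, array(7, dim(inner)), tolerance = 1e-12)
  img <- rand_pet(c(10, 10, 10), seed = 8)
  out2 <- apply_rigid(img, tf, g)
  expect_gte(min(out2$values), 0)
  expect_lte(max(out2$values), max(img$values) + 1e-12)
})

test_that("masks are resampled with nearest neighbor and stay binary", {
  g <- volume_grid(c(8, 8, 8), spacing = c(4, 4, 4), origin = c(-14, -14, -14))
  m <- rand_mask(g, 0.4, seed = 9)
  out <- apply_rigid(m, rigid_transform(c(2, 1, -1), c(3, 2, -2)), g)
  expect_s3_class(out, "binary_mask")
  expect_type(out$membership, "logical")
})
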