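test_that("derive_region boxes behave at the edge cases", {
  g <- volume_grid(c(16, 16, 16), spacing = c(4, 4, 4), origin = c(-30, -30, -30))
  a <- array(0, c(16, 16, 16))
  a[9, 9, 9] <- 5   # single hot voxel at world (2, 2, 2)
  img <- suv_image(a, g)
  r <- derive_region(img, fraction = 0.5, margin_mm = 40)
  expect_equal(r$box["lo", ], pmax(c(2, 2, 2) - 40, c(-30, -30, -30)))
  expect_equal(r$box["hi", ], pmin(c(2, 2, 2) + 40, c(30, 30, 30)))
  # fraction 0 gives the whole domain
  whole <- derive_region(img, fraction = 0)
  expect_equal(whole$box, petsubvol:::grid_extent(g))
  expect_error(derive_region(suv_image(array(0, c(16, 16, 16)), g)), "> 0")
})

test_that("the default registration region contains the ground-truth tumor", {
  ph <- quiet_phantom(group = "LRRD", seed = 21)
  r <- derive_region(ph$baseline_pet, 0.30, 40)
  hits <- which(ph$tumor_mask$membership)
  ijk <- arrayInd(hits, ph$tumor_mask$grid$shape) - 1L
  w <- petsubvol:::index_to_world(ph$tumor_mask$grid, ijk)
  expect_true(all(sweep(w, 2, r$box["lo", ], ">=") &
                  sweep(w, 2, r$box["hi", ], "<=")))
})

test_that("mutual information has the expected information-theoretic behavior", {
  img <- rand_pet(c(20, 20, 20), seed = 31)
  perm <- suv_image(array(sample(img$values), dim(img$values)), img$grid)
  expect_gte(mutual_information(img, img), mutual_information(img, perm))
  # symmetry
  other <- rand_pet(c(20, 20, 20), seed = 32)
  expect_equal(mutual_information(img, other), mutual_information(other, img),
               tolerance = 1e-12)
  # constant image: zero-entropy marginal
  const <- suv_image(array(3, c(20, 20, 20)), img$grid)
  expect_equal(mutual_information(const, img), 0)
  # non-negative
  expect_gte(mutual_information(img, other), 0)
})

test_that("MI of independent noise stays within the analytic estimator bias", {
  set.seed(33)
  g <- volume_grid(c(40, 40, 40), spacing = c(4, 4, 4), origin = c(-78, -78, -78))
  n <- prod(g$shape)
  a <- suv_image(array(runif(n, 0, 10), g$shape), g)
  b <- suv_image(array(runif(n, 0, 10), g$shape), g)
  bins <- 32
  bias <- (bins - 1)^2 / (2 * n)   # E[MI] for independent data
  mi <- mutual_information(a, b, bins = bins)
  expect_lt(mi, 3 * bias)
  expect_gte(mi, 0)
})

test_that("small regions trigger an instability warning", {
  img <- rand_pet(c(8, 8, 8), seed = 34)
  r <- structure(list(box = rbind(lo = c(-6, -6, -6), hi = c(6, 6, 6))),
                 class = "registration_region")
  expect_warning(mutual_information(img, img, r), "unstable")
})

test_that("self-registration returns the identity", {
  ph <- generate_patient(phantom_config(group = "CR", noise_sd = 0.05,
                                        seed = 41))
  region <- derive_region(ph$baseline_pet, 0.30, 40)
  reg <- register_rigid(ph$baseline_anat, ph$baseline_anat, region)
  expect_true(all(abs(reg$transform$translation) < 0.1))
  expect_true(all(abs(reg$transform$rotation) < 0.1))
  expect_true(reg$converged)
})

test_that("a planted repositioning transform is recovered", {
  true_t <- c(6, -4, 8); true_r <- c(3, 0, -2)
  ph <- generate_patient(phantom_config(group = "LRRD", noise_sd = 0.05,
                                        translation = true_t,
                                        rotation = true_r, seed = 42))
  region <- derive_region(ph$baseline_pet, 0.30, 40)
  reg <- register_rigid(ph$baseline_anat, ph$followup_anat, region)
  expect_true(all(abs(reg$transform$translation - true_t) < 2))
  expect_true(all(abs(reg$transform$rotation - true_r) < 1))
  expect_gt(reg$mi, 0)
})

test_that("translation-only registration recovers within half a voxel", {
  true_t <- c(5, -6, 3)
  ph <- generate_patient(phantom_config(group = "CR", noise_sd = 0.05,
                                        translation = true_t,
                                        rotation = c(0, 0, 0), seed = 43))
  region <- derive_region(ph$baseline_pet, 0.30, 40)
  reg <- register_rigid(ph$baseline_anat, ph$followup_anat, region,
                        lock_rotation = TRUE)
  expect_true(all(abs(reg$transform$translation - true_t) < 2))  # 0.5 voxel at 4 mm
  expect_equal(reg$transform$rotation, c(0, 0, 0))
})
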