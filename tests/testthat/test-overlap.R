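test_that("identical and disjoint masks hit the index extremes", {
  g <- volume_grid(c(6, 6, 6))
  m <- rand_mask(g, 0.3, seed = 71)
  self <- overlap_indices(m, m)
  expect_equal(unlist(self[, c("dice", "jaccard", "of", "vci", "vcr")]),
               c(dice = 1, jaccard = 1, of = 1, vci = 1, vcr = 1))
  a <- array(FALSE, c(6, 6, 6)); a[1:5] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[100:104] <- TRUE
  dis <- overlap_indices(binary_mask(a, g), binary_mask(b, g))
  expect_equal(unlist(dis[, c("dice", "jaccard", "of", "vci", "vcr")]),
               c(dice = 0, jaccard = 0, of = 0, vci = 0, vcr = 0))
})

test_that("the nested 8/4 example matches the brute-force enumeration", {
  g <- volume_grid(c(4, 4, 4))
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE        # 8 voxels
  b <- array(FALSE, c(4, 4, 4)); b[1:2, 1:2, 1] <- TRUE          # 4, subset
  ma <- binary_mask(a, g); mb <- binary_mask(b, g)
  r <- overlap_indices(ma, mb)
  o <- oracle_overlap(ma, mb)
  expect_equal(r$dice, 8 / 12)
  expect_equal(r$jaccard, 0.5)
  expect_equal(r$of, 1)
  expect_equal(r$vci, 0.5)
  expect_equal(r$vcr, 1)
  expect_equal(r$dice, o$dice)
  expect_equal(r$n_intersection, o$n_intersection)
})

test_that("index identities hold on random mask pairs", {
  g <- volume_grid(c(8, 8, 8))
  for (s in 1:100) {
    a <- rand_mask(g, runif(1, 0.05, 0.6), seed = 7000 + 2 * s)
    b <- rand_mask(g, runif(1, 0.05, 0.6), seed = 7001 + 2 * s)
    r <- overlap_indices(a, b)
    expect_lte(r$jaccard, r$dice + 1e-12)
    expect_lte(r$dice, r$of + 1e-12)
    expect_equal(r$dice, 2 * r$jaccard / (1 + r$jaccard), tolerance = 1e-12)
    expect_identical(round(r$vci * r$n_i), as.numeric(r$n_intersection))
    expect_identical(round(r$vcr * r$n_r), as.numeric(r$n_intersection))
    expect_true(all(unlist(r[, c("dice", "jaccard", "of", "vci", "vcr")]) >= 0))
    expect_true(all(unlist(r[, c("dice", "jaccard", "of", "vci", "vcr")]) <= 1))
  }
})

test_that("OF is 1 exactly when the smaller mask is contained in the larger", {
  g <- volume_grid(c(6, 6, 6))
  for (s in 1:50) {
    a <- rand_mask(g, 0.4, seed = 800 + s)
    b <- rand_mask(g, 0.15, seed = 900 + s)
    r <- overlap_indices(a, b)
    smaller <- if (r$n_i <= r$n_r) a else b
    larger <- if (r$n_i <= r$n_r) b else a
    contained <- all(larger$membership[smaller$membership])
    expect_identical(r$of == 1, contained)
  }
})

test_that("empty masks and grid mismatches are rejected", {
  g <- volume_grid(c(4, 4, 4))
  full <- rand_mask(g, 0.5, seed = 81)
  empty <- binary_mask(array(FALSE, c(4, 4, 4)), g)
  expect_error(overlap_indices(full, empty), "empty")
  g2 <- volume_grid(c(4, 4, 4), spacing = c(2, 2, 2))
  expect_error(overlap_indices(full, rand_mask(g2, 0.5, seed = 82)), "grid")
})

test_that("concordance classification uses the half-open kappa-style bins", {
  expect_equal(as.character(classify_concordance(c(0, 0.2, 0.20001, 0.4,
                                                   0.52, 0.6, 0.7, 0.8, 1))),
               c("very_low", "very_low", "low", "low", "moderate", "moderate",
                 "good", "good", "very_good"))
  expect_true(is.ordered(classify_concordance(0.5)))
  expect_error(classify_concordance(1.2), "\\[0, 1\\]")
  expect_error(classify_concordance(-0.1), "\\[0, 1\\]")
})

test_that("cohort tables aggregate per-patient overlaps correctly", {
  g <- volume_grid(c(6, 6, 6))
  a <- rand_mask(g, 0.4, seed = 91)
  one <- overlap_indices(a, a, i_label = "I40", r_label = "R40")
  tab <- cohort_overlap_table(one, "R40")
  expect_equal(nrow(tab), 5)        # one threshold x five indices
  expect_true(all(tab$sd == 0))     # single patient
  expect_true(all(tab$mean == 1))   # R40 equals I40 exactly
  # presence counts: equal masks overlap; disjoint ones do not
  b <- binary_mask(!a$membership, g)
  rows <- dplyr::bind_rows(
    overlap_indices(a, a, "I30", "R90"),
    overlap_indices(a, b, "I40", "R90"))
  counts <- overlap_presence_counts(rows, "R90")
  expect_equal(counts$n_overlap[counts$i_label == "I30"], 1L)
  expect_equal(counts$n_overlap[counts$i_label == "I40"], 0L)
  expect_equal(counts$label[counts$i_label == "I30"], "1 (100%)")
  expect_error(cohort_overlap_table(one[0, ], "R40"), "empty cohort")
})
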