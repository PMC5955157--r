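test_that("the normality omnibus statistic matches an independent reference", {
  # expected values computed with an independent omnibus-test implementation
  x8 <- c(1.2, 3.4, 2.2, 5.6, 4.4, 3.3, 2.1, 7.8)
  r8 <- dagostino_pearson(x8)
  expect_equal(r8$statistic, 1.839172894299, tolerance = 1e-9)
  expect_equal(r8$p, 0.398683883853, tolerance = 1e-9)
  u30 <- c(0.652019, 0.927480, 0.466139, 0.207110, 0.922714, 0.945857,
           0.134906, 0.899639, 0.292149, 0.128175, 0.118077, 0.759450,
           0.088443, 0.763152, 0.239619, 0.418784, 0.143018, 0.652670,
           0.457786, 0.393830, 0.804673, 0.459015, 0.691568, 0.781989,
           0.614881, 0.961391, 0.550878, 0.219013, 0.541880, 0.244557)
  r30 <- dagostino_pearson(u30)
  expect_equal(r30$statistic, 8.536070314152, tolerance = 1e-9)
  expect_equal(r30$p, 0.014009282168, tolerance = 1e-7)
  ln20 <- c(2.790124, 2.779969, 2.780464, 2.841343, 1.849194, 1.704504,
            1.363795, 0.826513, 3.231820, 5.974504, 1.760385, 1.738648,
            2.110265, 1.880407, 0.861556, 8.101801, 3.862057, 1.538248,
            3.447804, 1.914074)
  r20 <- dagostino_pearson(ln20)
  expect_equal(r20$statistic, 18.610845081341, tolerance = 1e-9)
  expect_equal(r20$p, 0.000090929822, tolerance = 1e-7)
})

test_that("the normality test is flagged unavailable below n = 8 and errors on constants", {
  r <- dagostino_pearson(c(1, 2, 3, 4, 5))
  expect_false(r$available)
  expect_true(is.na(r$p))
  expect_error(dagostino_pearson(rep(2, 10)), "constant")
})

test_that("the normality test rejects skewed samples and keeps its size", {
  set.seed(55)
  rej_null <- mean(replicate(400, dagostino_pearson(rnorm(60))$p < 0.05))
  expect_gt(rej_null, 0.02)
  expect_lt(rej_null, 0.09)
  rej_skew <- mean(replicate(200, dagostino_pearson(rlnorm(100, 0, 1))$p < 0.01))
  expect_gt(rej_skew, 0.95)
})

test_that("the exact Mann-Whitney path matches exhaustive enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")
  set.seed(56)
  for (n1 in 1:5) for (n2 in 1:5) {
    x <- rnorm(n1); y <- rnorm(n2)
    got <- mann_whitney(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, oracle_mw_p(x, y), tolerance = 1e-12,
                 info = sprintf("n1=%d n2=%d", n1, n2))
  }
})

test_that("Mann-Whitney is symmetric and handles degenerate samples", {
  set.seed(57)
  x <- rnorm(8); y <- rnorm(11)
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(a$u, 8 * 11 - b$u)
  expect_equal(a$p, b$p)
  # identical multisets: no evidence of a shift
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.9)
  expect_equal(mann_whitney(rep(2, 5), rep(2, 7))$p, 1)
})

test_that("the tie-corrected normal approximation agrees with the standard implementation", {
  set.seed(58)
  for (i in 1:20) {
    x <- sample(1:6, 25, replace = TRUE)
    y <- sample(1:7, 30, replace = TRUE)
    got <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                               exact = FALSE))
    expect_equal(got$method, "normal")
    expect_equal(got$u, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("sample summaries switch to median + range for non-normal data", {
  set.seed(59)
  s <- summarize_sample(rlnorm(100, 1, 1))
  expect_true(s$report_range)
  expect_false(s$normal)
  n <- summarize_sample(rnorm(200))
  expect_false(n$report_range)
  tiny <- summarize_sample(c(8.3, 23.5, 65.3))
  expect_true(tiny$report_range)    # untestable at n = 3, range reported
  expect_true(is.na(tiny$normal))
  one <- summarize_sample(5)
  expect_equal(one$mean, 5)
  expect_true(is.na(one$sd))
})

test_that("compare_groups produces one tested row per variable", {
  set.seed(60)
  d <- data.frame(group = rep(c("CR", "LRRD"), c(20, 25)),
                  mtv = c(rlnorm(20, log(9), 0.45), rlnorm(25, log(23), 0.45)),
                  suv = rnorm(45, 14, 4))
  cmp <- compare_groups(d, vars = c("mtv", "suv"))
  expect_s3_class(cmp, "group_comparison")
  expect_equal(nrow(cmp), 2)
  expect_true(all(cmp$u >= 0 & cmp$u <= 20 * 25))
  expect_true(all(cmp$p_value > 0 & cmp$p_value <= 1))
  td <- tidy(cmp)
  expect_named(td, c("variable", "u", "p_value", "method", "significant"))
  expect_error(compare_groups(data.frame(group = "A", x = 1), "x"), "2 levels")
})
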