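# Group-level statistics: D'Agostino-Pearson normality screening drives the
# reporting style (mean +/- SD, adding median + range when normality is
# rejected or untestable), and two-sided Mann-Whitney U tests compare
# baseline MTV, TLG and SUVmax between response groups at alpha = 0.05.
# P-values are reported unadjusted; no multiple-testing correction is
# applied across the group comparisons.

#' D'Agostino-Pearson omnibus normality test
#'
#' The K-squared statistic combines the transformed sample skewness
#' (D'Agostino 1970) and kurtosis (Anscombe-Glynn 1983) z-scores;
#' under normality K2 is approximately chi-squared with 2 degrees of
#' freedom. Requires n >= 8; below that the test is flagged unavailable
#' (`available = FALSE`, `p` is `NA`).
#'
#' @param x Numeric sample.
#' @return A list: `statistic` (K2), `p`, `n`, `available`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8)
    return(list(statistic = NA_real_, p = NA_real_, n = n, available = FALSE))
  if (sd(x) == 0) abort("normality test is undefined for a constant sample")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)

  # skewness z (D'Agostino)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe-Glynn)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  zk <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- zs^2 + zk^2
  list(statistic = k2, p = pchisq(k2, df = 2, lower.tail = FALSE),
       n = n, available = TRUE)
}

#' Mann-Whitney U test (two-sided)
#'
#' The U statistic is computed from midranks. When there are no ties and
#' `n1 * n2 <= 400` the p-value comes from the exact rank-sum distribution;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. If every value in both groups is identical the
#' p-value is 1 by contract.
#'
#' @param x,y Numeric samples for the two groups (both nonempty).
#' @return A list: `u` (U for group `x`), `p` (two-sided), `method`
#'   (`"exact"` or `"normal"`), `n1`, `n2`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both groups must be nonempty")
  all_v <- c(x, y)
  r <- rank(all_v)   # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_v)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 * n2 <= 400) {
    # exact rank-sum distribution (equivalent to enumerating all splits)
    p <- if (u > n1 * n2 / 2) {
      2 * pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * pwilcox(u, n1, n2)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    nn <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1   # all values identical across both groups
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(u = u, p = p, method = method, n1 = n1, n2 = n2)
}

#' Summarize a sample the way the cohort report does
#'
#' Always reports mean and SD; adds median and range when normality is
#' rejected at `alpha` or the normality test is unavailable (n < 8).
#'
#' @param x Numeric sample (n >= 1).
#' @param alpha Normality rejection level (default 0.05).
#' @return A one-row tibble: `n`, `mean`, `sd` (`NA` for n = 1), `median`,
#'   `min`, `max`, `normality_p`, `normal` (NA when untestable),
#'   `report_range` (whether median + range belong in the report).
#' @export
summarize_sample <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 1) abort("sample must contain at least one value")
  nt <- if (length(x) >= 8 && sd(x) > 0) dagostino_pearson(x)
        else list(p = NA_real_, available = FALSE)
  normal <- if (nt$available) nt$p >= alpha else NA
  tibble::tibble(
    n = length(x),
    mean = mean(x),
    sd = if (length(x) > 1) sd(x) else NA_real_,
    median = median(x),
    min = min(x),
    max = max(x),
    normality_p = nt$p,
    normal = normal,
    report_range = !isTRUE(normal)
  )
}

#' Compare a set of variables between two patient groups
#'
#' For each requested variable: per-group [summarize_sample()] summaries
#' and a two-sided [mann_whitney()] test, flagged significant at
#' `alpha = 0.05`. P-values are unadjusted.
#'
#' @param data A data frame with one row per patient.
#' @param vars Character vector of numeric column names to compare.
#' @param group Name of the grouping column (exactly two levels).
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `group_comparison`, one row per variable:
#'   the group labels, per-group `n`/`mean`/`sd`/`median`/`min`/`max`/
#'   `normality_p`, `u`, `p_value`, `method` and `significant`.
#' @export
compare_groups <- function(data, vars, group = "group", alpha = 0.05) {
  g <- data[[group]]
  lv <- sort(unique(as.character(g)))
  if (length(lv) != 2)
    abort(sprintf("grouping column must have exactly 2 levels, found %d",
                  length(lv)))
  rows <- purrr::map_dfr(vars, function(v) {
    a <- data[[v]][g == lv[1]]
    b <- data[[v]][g == lv[2]]
    sa <- summarize_sample(a, alpha); sb <- summarize_sample(b, alpha)
    mw <- mann_whitney(a, b)
    tibble::tibble(
      variable = v, group_a = lv[1], group_b = lv[2],
      n_a = sa$n, mean_a = sa$mean, sd_a = sa$sd, median_a = sa$median,
      min_a = sa$min, max_a = sa$max, normality_p_a = sa$normality_p,
      n_b = sb$n, mean_b = sb$mean, sd_b = sb$sd, median_b = sb$median,
      min_b = sb$min, max_b = sb$max, normality_p_b = sb$normality_p,
      u = mw$u, p_value = mw$p, method = mw$method,
      significant = mw$p < alpha
    )
  })
  class(rows) <- c("group_comparison", class(rows))
  attr(rows, "alpha") <- alpha
  rows
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%s vs %s), two-sided Mann-Whitney, alpha = %g, unadjusted p-values\n",
              x$group_a[1], x$group_b[1], attr(x, "alpha") %||% 0.05))
  NextMethod()
}

#' Tidy a group comparison
#'
#' @param x A [compare_groups()] result.
#' @param ... Unused.
#' @return A tibble with one row per variable: `variable`, `u`, `p_value`,
#'   `method`, `significant`.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble::as_tibble(x)[, c("variable", "u", "p_value", "method", "significant")]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
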