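# Distribution statistics for fold-change vectors: skewness, D'Agostino's
# omnibus normality test, and wrappers for the two-sample tests used to
# contrast coding and lncRNA fold-change distributions.

#' Sample skewness (moment definition)
#'
#' `g1 = m3 / m2^(3/2)` with `mk` the k-th central sample moment. The
#' bias-adjusted estimator `G1 = g1 * sqrt(n(n-1))/(n-2)` is available via
#' `adjusted = TRUE`.
#'
#' @param x numeric vector, n >= 3, finite, non-constant.
#' @param adjusted return the adjusted Fisher-Pearson G1 instead of g1.
#' @return Skewness estimate.
#' @export
sample_skewness <- function(x, adjusted = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("skewness requires n >= 3")
  if (any(!is.finite(x))) stop("non-finite values in x")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance")
  g1 <- mean((x - m)^3) / m2^1.5
  if (adjusted) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' D'Agostino K-squared omnibus normality test
#'
#' Combines D'Agostino's transformed skewness statistic `z_g1` with the
#' Anscombe-Glynn transformed kurtosis statistic `z_g2` into the omnibus
#' statistic `K2 = z_g1^2 + z_g2^2`, referred to a chi-squared distribution
#' with 2 df. A skewness-only two-sided Z test is reported alongside
#' (`p_skew`), since right-skew of a fold-change distribution is the feature
#' of interest.
#'
#' @param x numeric vector, n >= 20 (small-sample validity guard).
#' @return List of class `skewness_result`: `g1`, `z_g1`, `g2`, `z_g2`,
#'   `k2`, `p_value` (omnibus), `p_skew` (skewness-only, two-sided), `n`.
#' @export
dagostino_k2 <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) stop("dagostino_k2 requires n >= 20 (validity guard)")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero variance")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3

  # skewness transformation (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_g1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis transformation (Anscombe & Glynn 1983)
  e_g2 <- -6 / (n + 1)
  var_g2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xq <- (g2 - e_g2) / sqrt(var_g2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z_g2 <- ((1 - 2 / (9 * a)) -
             ((1 - 2 / a) / (1 + xq * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_g1^2 + z_g2^2
  structure(list(
    g1 = g1, z_g1 = z_g1, g2 = g2, z_g2 = z_g2, k2 = k2,
    p_value = pchisq(k2, df = 2, lower.tail = FALSE),
    p_skew = 2 * pnorm(abs(z_g1), lower.tail = FALSE),
    n = n, method = "D'Agostino K-squared omnibus test"
  ), class = "skewness_result")
}

test_result <- function(statistic, p_value, method, ...) {
  structure(c(list(statistic = unname(statistic), p_value = unname(p_value),
                   method = method), list(...)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = max |ECDF_x - ECDF_y|` with the asymptotic two-sided p-value; used
#' to compare the cumulative fold-change distributions of coding genes and
#' lncRNAs.
#'
#' @param x,y non-empty numeric vectors.
#' @return `test_result` with `statistic` (D) and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(x, y, alternative = "two.sided"))
  test_result(kt$statistic, kt$p.value, "two-sample Kolmogorov-Smirnov test")
}

#' Chi-squared test for two proportions
#'
#' Builds the 2x2 table `[[x1, n1-x1], [x2, n2-x2]]` and tests equality of
#' the two proportions (df = 1). Used e.g. to compare the fraction of
#' upregulated versus downregulated lncRNAs.
#'
#' @param x1,n1,x2,n2 successes and totals, `0 <= xi <= ni`.
#' @param yates apply Yates' continuity correction (default TRUE).
#' @return `test_result` with `statistic`, `p_value`, `df`, `table`, and
#'   `warning` (non-NULL when an expected cell is below 1).
#' @export
chi2_two_proportions <- function(x1, n1, x2, n2, yates = TRUE) {
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) stop("need 0 <= xi <= ni")
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  warn <- if (any(expected < 1)) "expected cell count < 1" else NULL
  ct <- suppressWarnings(chisq.test(tab, correct = yates))
  test_result(ct$statistic, ct$p.value, "chi-squared test of two proportions",
              df = 1L, table = tab, warning = warn)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing the probabilities of all tables (margins
#' fixed) whose hypergeometric probability does not exceed that of the
#' observed table — the conventional two-sided rule.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return `test_result` with `p_value`, `statistic` (the odds ratio
#'   estimate) and the table.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0)) stop("negative cell count")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate margin in 2x2 table")
  }
  ft <- fisher.test(table, alternative = "two.sided")
  test_result(unname(ft$estimate), ft$p.value, "Fisher's exact test",
              table = table)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance ("Student's") two-sided t-test by default; Welch's
#' unequal-variance version via `equal_variance = FALSE`.
#'
#' @param x,y numeric vectors, each n >= 2.
#' @param equal_variance pool the variances (default TRUE).
#' @return `test_result` with `statistic` (t), `p_value` and `df`.
#' @export
student_t_two_sample <- function(x, y, equal_variance = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (equal_variance && var(x) == 0 && var(y) == 0) {
    stop("zero pooled variance")
  }
  tt <- t.test(x, y, var.equal = equal_variance, alternative = "two.sided")
  test_result(tt$statistic, tt$p.value,
              if (equal_variance) "Student's two-sample t-test"
              else "Welch's two-sample t-test",
              df = unname(tt$parameter))
}

#' Gaussian kernel density and empirical CDF of a fold-change vector
#'
#' The density uses a Gaussian kernel with Silverman's rule-of-thumb
#' bandwidth by default and integrates to 1 (trapezoid rule) within 1e-3 on
#' a sufficiently wide grid. The ECDF is right-continuous and reaches 1 at
#' the sample maximum.
#'
#' @param values finite numeric vector, n >= 2.
#' @param bandwidth bandwidth rule or value passed to [stats::density()]'s
#'   `bw` (default `"nrd0"`, Silverman's rule).
#' @param n_grid number of grid points (default 512).
#' @param from,to grid limits; default extends 4 bandwidths past the range.
#' @return List with `density` (data.frame `x`, `y`) and `ecdf` (data.frame
#'   `x`, `y`, evaluated at the sorted unique values).
#' @export
density_and_ecdf <- function(values, bandwidth = "nrd0", n_grid = 512,
                             from = NULL, to = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need n >= 2")
  if (any(!is.finite(values))) stop("non-finite values")
  args <- list(x = values, bw = bandwidth, kernel = "gaussian", n = n_grid)
  if (!is.null(from)) args$from <- from
  if (!is.null(to)) args$to <- to
  d <- do.call(density, args)
  xs <- sort(unique(values))
  ec <- stats::ecdf(values)
  list(density = data.frame(x = d$x, y = d$y),
       ecdf = data.frame(x = xs, y = ec(xs)))
}
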