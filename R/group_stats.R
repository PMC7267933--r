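# Cross-sectional test battery: Welch t (from raw data or printed summary
# statistics), Pearson chi-square without continuity correction, Fisher's
# exact test, Kruskal-Wallis on ranks, Spearman rank correlation, Lilliefors
# normality test with a Monte-Carlo p-value, and Bonferroni control.
#
# Standard tests delegate to the corresponding stats:: implementations; the
# Welch t from summary statistics and the Lilliefors Monte-Carlo p are
# computed directly because no stats:: routine consumes those inputs.

#' Group summary statistics
#'
#' The triple (mean, SD, n) as printed in demographic tables, from which the
#' Welch t statistic is exactly recomputable.
#'
#' @param mean,sd,n Group mean, standard deviation (>= 0), and size (>= 2).
#' @return A `summary_stats` object.
#' @export
summary_stats <- function(mean, sd, n) {
  if (n < 2) lm_error("longmorph_domain_error", "n must be >= 2")
  if (sd < 0) lm_error("longmorph_domain_error", "sd must be >= 0")
  structure(list(mean = mean, sd = sd, n = n), class = "summary_stats")
}

as_summary_stats <- function(x) {
  if (inherits(x, "summary_stats")) return(x)
  x <- x[is.finite(x)]
  summary_stats(mean(x), stats::sd(x), length(x))
}

test_result <- function(method, statistic, df, p, estimate = NULL) {
  structure(list(method = method, statistic = statistic, df = df, p = p,
                 estimate = estimate),
            class = "cohort_test")
}

#' @export
print.cohort_test <- function(x, ...) {
  dfs <- if (length(x$df) == 2L) sprintf("df = (%.4g, %.4g)", x$df[1L],
                                         x$df[2L])
  else sprintf("df = %.4g", x$df)
  cat(sprintf("%s: statistic = %.5g, %s, p = %.4g\n", x$method, x$statistic,
              dfs, x$p))
  invisible(x)
}

#' Welch two-sample t test (unequal variances)
#'
#' Accepts either raw numeric vectors or [summary_stats()] objects, so the
#' statistic can be recomputed from a table's printed mean/SD/n cells:
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p.
#'
#' @param a,b Numeric vectors or `summary_stats`.
#' @return A `cohort_test`.
#' @examples
#' welch_t(summary_stats(13.4, 2.9, 172), summary_stats(16.1, 4.0, 85))
#' @export
welch_t <- function(a, b) {
  a <- as_summary_stats(a); b <- as_summary_stats(b)
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  if (va + vb == 0)
    return(test_result("Welch two-sample t", 0, a$n + b$n - 2, 1))
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  test_result("Welch two-sample t", t, df,
              2 * stats::pt(abs(t), df, lower.tail = FALSE),
              estimate = a$mean - b$mean)
}

check_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    lm_error("longmorph_domain_error",
             "contingency table must hold non-negative integers")
  counts
}

#' Pearson chi-square test of independence (no continuity correction)
#'
#' `chi2 = sum (O - E)^2 / E` with expected counts from the margins and
#' `df = (r - 1)(c - 1)`. No Yates correction is applied, matching the way
#' categorical statistics are conventionally printed alongside demographic
#' tables.
#'
#' @param counts An r x c matrix of non-negative integer counts with positive
#'   margins.
#' @return A `cohort_test`.
#' @examples
#' pearson_chi2(matrix(c(120, 48, 52, 37), 2)) # 4.443
#' @export
pearson_chi2 <- function(counts) {
  counts <- check_contingency(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    lm_error("longmorph_domain_error", "zero margin in contingency table")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  test_result("Pearson chi-square", unname(ht$statistic),
              unname(ht$parameter), ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p obtained by summing hypergeometric probabilities of all
#' margin-preserving tables no more probable than the observed one. Tables
#' larger than 2x2 are dispatched to [pearson_chi2()].
#'
#' @param counts A 2x2 matrix of non-negative integer counts.
#' @return A `cohort_test` (the statistic slot carries the odds ratio
#'   estimate).
#' @export
fisher_exact_2x2 <- function(counts) {
  counts <- check_contingency(counts)
  if (!all(dim(counts) == c(2L, 2L))) return(pearson_chi2(counts))
  ht <- stats::fisher.test(counts)
  test_result("Fisher exact (2x2)", unname(ht$estimate), NA_real_,
              ht$p.value)
}

#' Kruskal-Wallis rank analysis of variance
#'
#' Mid-rank H statistic with tie correction and a chi-square approximation on
#' k - 1 degrees of freedom. With all observations equal the statistic is 0
#' and p is 1.
#'
#' @param samples List of numeric vectors, one per group (>= 2 groups).
#' @return A `cohort_test`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2L)
    lm_error("longmorph_domain_error", "need >= 2 groups")
  x <- unlist(samples, use.names = FALSE)
  if (length(x) < 3L)
    lm_error("longmorph_domain_error", "need >= 3 observations in total")
  if (length(unique(x)) == 1L)
    return(test_result("Kruskal-Wallis", 0, length(samples) - 1L, 1))
  g <- factor(rep.int(seq_along(samples), lengths(samples)))
  ht <- stats::kruskal.test(x, g)
  test_result("Kruskal-Wallis", unname(ht$statistic), unname(ht$parameter),
              ht$p.value)
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of mid-ranks; two-sided p from the t approximation
#' `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return A `cohort_test` (the statistic slot carries rho).
#' @export
spearman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) lm_error("longmorph_domain_error", "need >= 3 pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    lm_error("longmorph_domain_error", "zero rank variance")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  test_result("Spearman rank correlation", unname(ht$estimate), n - 2L,
              ht$p.value, estimate = unname(ht$estimate))
}

lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  pz <- stats::pnorm(z)
  max(seq_len(n) / n - pz, pz - (seq_len(n) - 1L) / n)
}

#' Lilliefors test of normality (Monte-Carlo p)
#'
#' Kolmogorov-Smirnov distance between the empirical CDF and the normal
#' distribution with estimated mean and SD. Because the parameters are
#' estimated, the null distribution is obtained by Monte-Carlo simulation of
#' standard-normal samples of the same size (the statistic is affine
#' invariant), with `p = (1 + #{D_mc >= D_obs}) / (n_mc + 1)`.
#'
#' @param x Numeric vector, n >= 5, nonzero variance.
#' @param n_mc Number of Monte-Carlo null replicates.
#' @param seed Optional seed for the Monte-Carlo draw (reproducible p).
#' @return A `cohort_test`.
#' @export
lilliefors <- function(x, n_mc = 10000L, seed = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5L) lm_error("longmorph_domain_error", "need n >= 5")
  if (stats::sd(x) == 0)
    lm_error("longmorph_domain_error", "zero variance")
  d_obs <- lilliefors_statistic(x)
  if (!is.null(seed)) set.seed(seed)
  sims <- matrix(stats::rnorm(n * n_mc), n, n_mc)
  d_null <- apply(sims, 2L, lilliefors_statistic)
  p <- (1 + sum(d_null >= d_obs)) / (n_mc + 1)
  test_result("Lilliefors (Monte-Carlo)", d_obs, NA_real_, p)
}

#' Bonferroni correction
#'
#' `adjusted = min(1, p * m)` with `m` defaulting to the number of tests, and
#' significance flags at the familywise level `alpha`.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param m Family size; default `length(p_values)`.
#' @param alpha Familywise level for the flags.
#' @return List with `adjusted` and logical `significant`.
#' @export
bonferroni <- function(p_values, m = NULL, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    lm_error("longmorph_domain_error", "p-values must lie in [0, 1]")
  if (is.null(m)) m <- length(p_values)
  adjusted <- pmin(1, p_values * m)
  list(adjusted = adjusted, significant = !is.na(adjusted) & adjusted < alpha,
       m = m)
}
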