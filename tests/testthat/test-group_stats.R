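test_that("Welch t from summaries equals Welch t from raw data", {
  set.seed(2)
  a <- rnorm(25, 10, 2)
  b <- rnorm(40, 11, 4)
  t_raw <- welch_t(a, b)
  t_sum <- welch_t(summary_stats(mean(a), sd(a), length(a)),
                   summary_stats(mean(b), sd(b), length(b)))
  expect_equal(t_raw$statistic, t_sum$statistic, tolerance = 1e-12)
  expect_equal(t_raw$p, t_sum$p, tolerance = 1e-12)
  ht <- stats::t.test(a, b)
  expect_equal(t_raw$statistic, unname(ht$statistic), tolerance = 1e-10)
  expect_equal(t_raw$df, unname(ht$parameter), tolerance = 1e-10)
  expect_equal(t_raw$p, ht$p.value, tolerance = 1e-10)
  # antisymmetry
  t_rev <- welch_t(b, a)
  expect_equal(t_rev$statistic, -t_raw$statistic)
  expect_equal(t_rev$p, t_raw$p)
  expect_equal(welch_t(summary_stats(5, 1, 10),
                       summary_stats(5, 1, 10))$statistic, 0)
})

test_that("Welch t maintains its nominal level under unequal variances", {
  set.seed(42)
  rej <- mean(vapply(1:3000, function(i) {
    welch_t(rnorm(15, 0, 1), rnorm(40, 0, 3))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

test_that("Pearson chi-square matches the 2x2 closed form", {
  set.seed(6)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 30) + 1L, 2L, 2L)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(pearson_chi2(tab)$statistic, closed, tolerance = 1e-10)
  }
  # proportional rows are exactly independent
  expect_equal(pearson_chi2(matrix(c(10, 5, 20, 10), 2))$statistic, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "longmorph_domain_error")
})

test_that("Fisher exact p equals brute-force hypergeometric enumeration", {
  tab <- matrix(c(2, 8, 8, 2), 2L, 2L)
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(support, r1, n - r1, c1)
  p_obs <- dhyper(tab[1, 1], r1, n - r1, c1)
  oracle <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  expect_equal(fisher_exact_2x2(tab)$p, oracle, tolerance = 1e-9)
  # proportional rows: the observed table is the most probable one
  expect_equal(fisher_exact_2x2(matrix(c(10, 5, 10, 5), 2))$p, 1)
  # transposition invariance
  tab2 <- matrix(c(7, 3, 2, 11), 2L)
  expect_equal(fisher_exact_2x2(tab2)$p, fisher_exact_2x2(t(tab2))$p)
})

test_that("Kruskal-Wallis matches a brute-force rank computation", {
  samples <- list(c(1.2, 3.4, 2.2), c(2.8, 5.1, 4.4, 6.0), c(0.5, 1.9))
  x <- unlist(samples)
  g <- rep(seq_along(samples), lengths(samples))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(samples)) - 3 * (N + 1)
  expect_equal(kruskal_wallis(samples)$statistic, H, tolerance = 1e-10)
  # tie-corrected case against the standard implementation
  samples_t <- list(c(1, 2, 2, 3), c(2, 4, 4), c(1, 5, 6))
  ht <- stats::kruskal.test(unlist(samples_t),
                            rep(1:3, lengths(samples_t)))
  expect_equal(kruskal_wallis(samples_t)$statistic, unname(ht$statistic))
  # all observations equal
  degen <- kruskal_wallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p, 1)
})

test_that("two-group Kruskal-Wallis equals the squared standardized rank sum", {
  set.seed(10)
  a <- rnorm(8); b <- rnorm(11, 0.5)
  H <- kruskal_wallis(list(a, b))$statistic
  r <- rank(c(a, b))
  N <- length(r)
  R1 <- sum(r[seq_along(a)])
  z <- (R1 - length(a) * (N + 1) / 2) /
    sqrt(length(a) * length(b) * (N + 1) / 12)
  expect_equal(H, z^2, tolerance = 1e-10)
})

test_that("Spearman correlation composes ranks with Pearson", {
  expect_equal(spearman(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman(1:10, -(1:10)^2)$statistic, -1)
  x <- c(1, 2, 2, 3, 5, 5)
  y <- c(2, 1, 4, 4, 6, 7)
  rho <- stats::cor(rank(x), rank(y))
  res <- spearman(x, y)
  expect_equal(res$statistic, rho, tolerance = 1e-12)
  tt <- rho * sqrt((6 - 2) / (1 - rho^2))
  expect_equal(res$p, 2 * stats::pt(abs(tt), 4, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(spearman(rep(1, 5), 1:5), class = "longmorph_domain_error")
})

test_that("Lilliefors statistic matches the reference implementation", {
  library(nortest)
  set.seed(14)
  for (i in 1:5) {
    x <- rgamma(60, shape = 2)
    expect_equal(lilliefors(x, n_mc = 100, seed = 1)$statistic,
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-12)
  }
  # affine invariance
  x <- rnorm(50)
  expect_equal(lilliefors(3 * x - 7, n_mc = 100, seed = 2)$statistic,
               lilliefors(x, n_mc = 100, seed = 2)$statistic,
               tolerance = 1e-12)
})

test_that("Lilliefors Monte-Carlo p is calibrated and has power", {
  set.seed(33)
  rej <- mean(vapply(1:400, function(i)
    lilliefors(rnorm(40), n_mc = 300)$p < 0.05, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
  low_p <- mean(vapply(1:20, function(i)
    lilliefors(runif(200), n_mc = 500)$p < 0.05, logical(1)))
  expect_gt(low_p, 0.7)
})

test_that("Bonferroni adjustment caps at one and flags at alpha", {
  out <- bonferroni(c(0.001), m = 50)
  expect_equal(out$adjusted, 0.05)
  expect_false(out$significant)
  expect_equal(bonferroni(c(0.5), m = 10)$adjusted, 1)
  expect_equal(bonferroni(c(0.2, 0.01), m = 1)$adjusted, c(0.2, 0.01))
  out2 <- bonferroni(c(0.001, 0.2, 0.04))
  expect_equal(out2$adjusted, pmin(1, c(0.003, 0.6, 0.12)))
  expect_identical(out2$significant, c(TRUE, FALSE, FALSE))
})
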