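test_that("reference normalization follows the ratio formula", {
  ref <- normalization_reference("ICV", 1459.3)
  expect_equal(normalize_to_reference(100, 1459.3, ref), 100)
  expect_equal(normalize_to_reference(100, 1400, ref), 104.2357,
               tolerance = 1e-6)
  expect_equal(normalize_to_reference(0, 1234, ref), 0)
  expect_error(normalize_to_reference(100, -3, ref),
               class = "longmorph_domain_error")
  # scale equivariance
  set.seed(2)
  v <- runif(20, 50, 150)
  cc <- runif(20, 0, 3)
  expect_equal(normalize_to_reference(cc * v, 1400, ref),
               cc * normalize_to_reference(v, 1400, ref))
})

test_that("noiseless covariate model is recovered exactly", {
  n <- 30
  set.seed(5)
  age <- runif(n, 50, 80)
  edu <- sample(8:20, n, replace = TRUE)
  d <- data.frame(subject_id = sprintf("C%02d", 1:n), group = "CTRL",
                  sex = "M", education = edu, baseline_age = age,
                  icv = 1459.3, visit_index = 0L, time_from_baseline = 0,
                  roi = 120 - 2 * age + 0.5 * edu,
                  stringsAsFactors = FALSE)
  tab <- long_table(d, region_dictionary("roi", "volume"))
  m <- fit_control_covariate_model(tab, "roi")
  expect_equal(unname(m$gamma), c(120, -2, 0.5), tolerance = 1e-9)
})

test_that("noisy covariate slopes fall within 3 analytic SEs", {
  n <- 200
  set.seed(8)
  age <- runif(n, 50, 80)
  edu <- round(runif(n, 8, 22))
  y <- 100 - 1.5 * age + 0.8 * edu + rnorm(n, 0, 5)
  d <- data.frame(subject_id = sprintf("C%03d", 1:n), group = "CTRL",
                  sex = "F", education = edu, baseline_age = age,
                  icv = 1459.3, visit_index = 0L, time_from_baseline = 0,
                  roi = y, stringsAsFactors = FALSE)
  tab <- long_table(d, region_dictionary("roi", "volume"))
  m <- fit_control_covariate_model(tab, "roi")
  X <- cbind(1, age, edu)
  se <- 5 * sqrt(diag(solve(crossprod(X))))
  expect_lt(abs(m$gamma[["age"]] + 1.5), 3 * se[2L])
  expect_lt(abs(m$gamma[["edu"]] - 0.8), 3 * se[3L])
})

test_that("degenerate covariate designs are rejected", {
  d <- tiny_table()$data[1:2, ]
  tab <- tiny_table(); tab$data <- d
  expect_error(fit_control_covariate_model(tab, "brain_volume"),
               class = "longmorph_singular_error")
  # constant age and education among controls
  n <- 5
  d <- data.frame(subject_id = sprintf("C%d", 1:n), group = "CTRL", sex = "M",
                  education = 12, baseline_age = 66, icv = 1450,
                  visit_index = 0L, time_from_baseline = 0, roi = rnorm(n, 100),
                  stringsAsFactors = FALSE)
  tab <- long_table(d, region_dictionary("roi", "volume"))
  expect_error(fit_control_covariate_model(tab, "roi"),
               class = "longmorph_singular_error")
})

test_that("covariate correction recenters at the reference covariates", {
  m <- structure(list(region = "roi",
                      gamma = c(`(Intercept)` = 0, age = -2, edu = 0),
                      x_age_ref = 66.7, x_edu_ref = 14.3,
                      include_sex = FALSE, sex_ref = NULL,
                      n = 10L, residual_sd = 1),
                 class = "covariate_model")
  expect_equal(apply_covariate_correction(100, 66.7, 14.3, m), 100)
  expect_equal(apply_covariate_correction(100, 68.7, 14.3, m), 104)
  m0 <- m; m0$gamma[c("age", "edu")] <- 0
  v <- runif(10, 50, 150)
  expect_equal(apply_covariate_correction(v, runif(10, 50, 80),
                                          runif(10, 8, 20), m0), v)
})

test_that("correction is exact on the fitting population", {
  # controls-only table: mean corrected value equals the model's prediction
  # at the reference covariates
  n <- 40
  set.seed(11)
  d <- data.frame(subject_id = sprintf("C%02d", 1:n), group = "CTRL",
                  sex = "M", education = round(runif(n, 8, 20)),
                  baseline_age = runif(n, 50, 80), icv = rnorm(n, 1459, 100),
                  visit_index = 0L, time_from_baseline = 0,
                  stringsAsFactors = FALSE)
  d$roi <- 100 - 1.2 * d$baseline_age + 0.4 * d$education + rnorm(n, 0, 3)
  tab <- long_table(d, region_dictionary("roi", "volume"))
  norm <- normalize_table(tab)
  res <- correct_table(norm)
  m <- res$models$roi
  pred_at_ref <- m$gamma[["(Intercept)"]] + m$gamma[["age"]] * m$x_age_ref +
    m$gamma[["edu"]] * m$x_edu_ref
  expect_equal(mean(res$table$data$roi), unname(pred_at_ref),
               tolerance = 1e-9)
})

test_that("provenance flags forbid double normalization and correction", {
  gen <- generate_cohort(roi_config(), seed = 2)
  norm <- normalize_table(gen$table)
  expect_error(normalize_table(norm), class = "longmorph_integrity_error")
  corr <- correct_table(norm)
  expect_error(correct_table(corr$table),
               class = "longmorph_integrity_error")
  expect_error(correct_table(gen$table),
               class = "longmorph_integrity_error")
})

test_that("thickness regions are normalized to subject mean thickness", {
  gen <- generate_cohort(synthetic_config(
    n_per_group = c(CTRL = 10, PDN = 10, PDCI = 10)), seed = 6)
  norm <- normalize_table(gen$table)
  d0 <- gen$table$data
  dn <- norm$data
  base <- d0[d0$visit_index == 0L, ]
  mt_ref <- mean(base$mean_thickness)
  mt_subj <- base$mean_thickness[match(d0$subject_id, base$subject_id)]
  expect_equal(dn$caudal_acc, d0$caudal_acc * mt_ref / mt_subj)
  # normalized thickness stays on the mm scale of the cohort mean
  expect_true(all(dn$caudal_acc > 1 & dn$caudal_acc < 5, na.rm = TRUE))
  # volumes use ICV
  icv_ref <- mean(base$icv)
  expect_equal(dn$brain_volume, d0$brain_volume * icv_ref / d0$icv)
})

test_that("hemisphere averaging is the arithmetic mean and flags missing sides", {
  v <- c(acc_lh = 2.4, acc_rh = 2.6, ins_lh = 3.0)
  expect_warning(out <- hemisphere_average(v), "ins")
  expect_equal(out[["acc"]], 2.5)
  expect_true(is.na(out[["ins"]]))
})

test_that("hemisphere averaging commutes with linear correction", {
  m <- structure(list(region = "r", gamma = c(`(Intercept)` = 0, age = -0.01,
                                              edu = 0.02),
                      x_age_ref = 66.7, x_edu_ref = 14.3,
                      include_sex = FALSE, sex_ref = NULL, n = 10L,
                      residual_sd = 1),
                 class = "covariate_model")
  set.seed(13)
  for (i in 1:5) {
    v <- c(r_lh = runif(1, 2, 3), r_rh = runif(1, 2, 3))
    age <- runif(1, 50, 80); edu <- runif(1, 8, 20)
    a <- apply_covariate_correction(hemisphere_average(v), age, edu, m)
    b <- hemisphere_average(vapply(v, apply_covariate_correction, numeric(1),
                                   age = age, education = edu, model = m))
    expect_equal(unname(a), unname(b))
  }
})

test_that("percent deviation uses the signed ratio convention", {
  expect_equal(percent_deviation(97, 100), -3)
  expect_equal(percent_deviation(100, 100), 0)
  expect_equal(percent_deviation(105, 100), 5)
  expect_error(percent_deviation(10, 0), class = "longmorph_domain_error")
})
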