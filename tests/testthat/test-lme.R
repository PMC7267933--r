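test_that("the knotted age transform is zero at and below the knot", {
  expect_equal(piecewise_age(50, 60), 0)
  expect_equal(piecewise_age(60, 60), 0)
  expect_equal(piecewise_age(70, 60), 10)
  expect_equal(piecewise_age(c(45, 60, 61.5), 60), c(0, 0, 1.5))
  expect_error(piecewise_age(50, 30), class = "longmorph_config_error")
})

test_that("the design matrix follows the fixed 8-column layout", {
  d <- tiny_table()$data
  d$baseline_age <- rep(c(65, 70, 72), each = 2L)
  tab <- long_table(d, tiny_table()$regions)
  tab$provenance <- "normalized"
  des <- build_design(tab, "brain_volume")
  expect_identical(ncol(des$X), 8L)
  # control, baseline age 65, education 16, visit at t = 0
  i <- which(des$subject == "C1" & des$time == 0)
  expect_equal(unname(des$X[i, ]), c(1, 0, 0, 0, 0, 0, 5, 16))
  # PDN subject at t = 1.1: G1 and t*G1 set, G2 columns zero
  j <- which(des$subject == "P1" & des$time > 0)
  expect_equal(unname(des$X[j, 2:6]), c(1.1, 1, 1.1, 0, 0))
  # the layout does not depend on which groups are present
  ctrl_only <- tab
  ctrl_only$data <- tab$data[tab$data$group == "CTRL", ]
  expect_identical(ncol(build_design(ctrl_only, "brain_volume")$X), 8L)
  # G1 * G2 == 0 elementwise
  expect_true(all(des$X[, 3] * des$X[, 5] == 0))
})

test_that("near-noiseless data returns the generating coefficients", {
  beta <- c(100, -1, -2, -0.3, -3, -0.5, -0.2, 0.1)
  cfg <- roi_config(beta = beta, sd0 = 0, sd1 = 0, corr = 0,
                    residual_sd = 1e-6, retention = full_retention(),
                    icv_mean_sd = c(1459.3, 0))
  gen <- generate_cohort(cfg, seed = 31)
  fit <- fit_lme(build_design(normalize_table(gen$table), "roi"))
  expect_equal(unname(fit$beta), beta, tolerance = 1e-6)
})

test_that("estimates agree with the reference REML implementation", {
  library(lme4)
  gen <- generate_cohort(roi_config(n = c(CTRL = 40, PDN = 40, PDCI = 40)),
                         seed = 17)
  norm <- normalize_table(gen$table)
  fit <- fit_lme(build_design(norm, "roi"))
  d <- norm$data
  d$pdn <- as.numeric(d$group == "PDN")
  d$pdci <- as.numeric(d$group == "PDCI")
  d$aok <- pmax(d$baseline_age - 60, 0)
  d$t <- d$time_from_baseline
  m <- lme4::lmer(roi ~ t + pdn + t:pdn + pdci + t:pdci + aok + education +
                    (1 + t | subject_id), data = d, REML = TRUE)
  fe <- lme4::fixef(m)[c("(Intercept)", "t", "pdn", "t:pdn", "pdci",
                         "t:pdci", "aok", "education")]
  expect_equal(unname(fit$beta), unname(fe), tolerance = 1e-4)
  expect_equal(sqrt(fit$sigma2), stats::sigma(m), tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(m))
  expect_equal(fit$psi[1, 1], vc$vcov[1], tolerance = 1e-3)
  expect_equal(fit$psi[2, 2], vc$vcov[2], tolerance = 1e-3)
  expect_equal(fit$psi[1, 2], vc$vcov[3], tolerance = 1e-2)
  se_ours <- sqrt(diag(fit$cov_beta))
  se_lme4 <- sqrt(diag(as.matrix(vcov(m))))[c(1, 2, 3, 7, 4, 8, 5, 6)]
  expect_equal(unname(se_ours), unname(se_lme4), tolerance = 1e-3)
})

test_that("slope recovery stays within sampling error at moderate n", {
  beta <- c(100, -0.5, -0.8, -0.01, -1.2, -0.005, -0.3, 0.05)
  gen <- generate_cohort(roi_config(n = c(CTRL = 100, PDN = 100, PDCI = 100)),
                         seed = 55)
  fit <- fit_lme(build_design(normalize_table(gen$table), "roi"))
  for (nm in c("time", "time:PDN", "time:PDCI")) {
    truth <- beta[match(nm, names(fit$beta))]
    expect_lt(abs(fit$beta[[nm]] - truth),
              3 * sqrt(fit$cov_beta[nm, nm]))
  }
})

test_that("degenerate designs raise actionable errors", {
  gen <- generate_cohort(roi_config(), seed = 8)
  tab <- normalize_table(gen$table)
  # baseline-only data: the slope variance (and the time effects) are
  # unidentifiable
  tab0 <- tab
  tab0$data <- tab$data[tab$data$visit_index == 0L, ]
  des0 <- build_design(tab0, "roi")
  expect_error(fit_lme(des0), "intercept", class = "longmorph_domain_error")
  expect_error(fit_lme(des0, random = "intercept"), "rank",
               class = "longmorph_domain_error")
  # all-missing outcome
  tab_na <- tab
  tab_na$data$roi <- NA_real_
  expect_error(build_design(tab_na, "roi"),
               class = "longmorph_domain_error")
})

test_that("random-intercept-only mode matches the reference implementation", {
  library(lme4)
  gen <- generate_cohort(roi_config(n = c(CTRL = 30, PDN = 30, PDCI = 30),
                                    sd1 = 0, corr = 0,
                                    retention = full_retention()),
                         seed = 26)
  norm <- normalize_table(gen$table)
  fit <- fit_lme(build_design(norm, "roi"), random = "intercept")
  expect_equal(fit$psi[2, 2], 0)
  d <- norm$data
  d$pdn <- as.numeric(d$group == "PDN")
  d$pdci <- as.numeric(d$group == "PDCI")
  d$aok <- pmax(d$baseline_age - 60, 0)
  d$t <- d$time_from_baseline
  m <- lme4::lmer(roi ~ t + pdn + t:pdn + pdci + t:pdci + aok + education +
                    (1 | subject_id), data = d, REML = TRUE)
  fe <- lme4::fixef(m)[c("(Intercept)", "t", "pdn", "t:pdn", "pdci",
                         "t:pdci", "aok", "education")]
  expect_equal(unname(fit$beta), unname(fe), tolerance = 1e-5)
  expect_equal(sqrt(fit$sigma2), stats::sigma(m), tolerance = 1e-4)
  expect_equal(fit$psi[1, 1], as.data.frame(lme4::VarCorr(m))$vcov[1],
               tolerance = 1e-3)
})

test_that("the slope-equality contrast has DF1 = 2 and is affine invariant", {
  gen <- generate_cohort(roi_config(n = c(CTRL = 30, PDN = 30, PDCI = 30)),
                         seed = 23)
  norm <- normalize_table(gen$table)
  fit <- fit_lme(build_design(norm, "roi"))
  ct <- contrast_F_test(fit)
  expect_identical(ct$DF1, 2L)
  expect_identical(ct$DF2, fit$df_residual)
  # y -> a*y + b leaves the F statistic unchanged
  tab2 <- norm
  tab2$data$roi <- -3.2 * tab2$data$roi + 400
  fit2 <- fit_lme(build_design(tab2, "roi"))
  ct2 <- contrast_F_test(fit2)
  expect_equal(ct2$F, ct$F, tolerance = 1e-3)
  expect_error(contrast_F_test(fit, L = matrix(0, 2, 8)),
               class = "longmorph_contrast_error")
  expect_error(contrast_F_test(fit, L = matrix(1, 1, 5)),
               class = "longmorph_contrast_error")
})

test_that("Satterthwaite denominator df matches lmerTest", {
  library(lmerTest)
  gen <- generate_cohort(roi_config(n = c(CTRL = 25, PDN = 25, PDCI = 25)),
                         seed = 12)
  norm <- normalize_table(gen$table)
  fit <- fit_lme(build_design(norm, "roi"))
  d <- norm$data
  d$pdn <- as.numeric(d$group == "PDN")
  d$pdci <- as.numeric(d$group == "PDCI")
  d$aok <- pmax(d$baseline_age - 60, 0)
  d$t <- d$time_from_baseline
  m <- lmerTest::lmer(roi ~ t + pdn + t:pdn + pdci + t:pdci + aok +
                        education + (1 + t | subject_id), data = d)
  # multi-df slope contrast (lmerTest coef order: t:pdn, t:pdci last)
  ours <- contrast_F_test(fit, df_method = "satterthwaite")
  L4 <- rbind(c(0, 0, 0, 0, 0, 0, 1, 0), c(0, 0, 0, 0, 0, 0, 0, 1))
  ref <- lmerTest::contest(m, L4)
  expect_equal(ours$F, ref$`F value`, tolerance = 1e-3)
  expect_equal(ours$DF2, ref$DenDF, tolerance = 0.02)
  # single-df contrast
  ours1 <- contrast_F_test(fit, L = matrix(c(0, 1, rep(0, 6)), 1),
                           df_method = "satterthwaite")
  ref1 <- lmerTest::contest(m, c(0, 1, rep(0, 6)))
  expect_equal(ours1$DF2, ref1$DenDF, tolerance = 0.02)
})

test_that("slope tables report per-group rates and display units", {
  gen <- generate_cohort(synthetic_config(
    n_per_group = c(CTRL = 20, PDN = 20, PDCI = 20)), seed = 3)
  norm <- normalize_table(gen$table)
  fits <- list(
    brain_volume = fit_lme(build_design(norm, "brain_volume")),
    caudal_acc = fit_lme(build_design(norm, "caudal_acc")))
  kinds <- c(brain_volume = "volume", caudal_acc = "thickness")
  st <- slope_table(fits, region_kinds = kinds)
  expect_identical(nrow(st), 2L)
  expect_identical(st$DF1, c(2L, 2L))
  fit <- fits$brain_volume
  expect_equal(st$rate_pdn[1],
               fit$beta[["time"]] + fit$beta[["time:PDN"]])
  expect_identical(format_rate(-0.028, "thickness"), "-28 um/y")
  expect_identical(format_rate(-5, "volume"), "-5 cm^3/y")
})
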