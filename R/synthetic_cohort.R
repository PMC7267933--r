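# Synthetic longitudinal cohort generator.
#
# Emulates the statistical structure the downstream analyses assume: three
# groups (healthy controls, cognitively normal PD, cognitively impaired PD),
# group-specific baseline deficits and atrophy rates, a knotted age effect
# (negligible below the knot, linear above), per-subject random intercept and
# slope, residual noise, and monotone study drop-out with the observed
# cumulative retention of a multi-year follow-up design.

# cumulative retention per visit (baseline included), from observed counts
# CTRL 85 -> 66/37/11/0, PDN 80 -> 63/26/16/6, PDCI 92 -> 66/28/18/3
.DEFAULT_RETENTION <- list(
  CTRL = c(1, 66 / 85, 37 / 85, 11 / 85, 0),
  PDN  = c(1, 63 / 80, 26 / 80, 16 / 80, 6 / 80),
  PDCI = c(1, 66 / 92, 28 / 92, 18 / 92, 3 / 92)
)

#' Random-effects covariance from SDs and correlation
#'
#' @param sd_intercept,sd_slope Standard deviations of the per-subject random
#'   intercept and slope (outcome units, outcome units per year).
#' @param corr Intercept-slope correlation.
#' @return A 2x2 covariance matrix.
#' @export
rand_cov <- function(sd_intercept, sd_slope, corr = 0) {
  m <- matrix(c(sd_intercept^2, corr * sd_intercept * sd_slope,
                corr * sd_intercept * sd_slope, sd_slope^2), 2L, 2L)
  m
}

#' Generative spec for one synthetic region
#'
#' @param kind `"volume"`, `"area"` or `"thickness"`.
#' @param beta Fixed effects in the 8-column design order: intercept, time,
#'   PD-N indicator, time x PD-N, PD-CI indicator, time x PD-CI,
#'   age-above-knot, education.
#' @param random_cov 2x2 PSD covariance of the per-subject random
#'   (intercept, slope); see [rand_cov()].
#' @param residual_sd Residual SD in outcome units.
#' @param units Display units; defaults by kind.
#' @return A region spec list for [synthetic_config()].
#' @export
region_spec <- function(kind, beta, random_cov, residual_sd, units = NULL) {
  list(kind = kind, beta = beta, random_cov = random_cov,
       residual_sd = residual_sd,
       units = if (is.null(units))
         c(volume = "cm^3", area = "mm^2", thickness = "mm")[kind] else units)
}

default_region_specs <- function() {
  list(
    brain_volume = region_spec("volume",
      beta = c(1250, -1.5, -25, 0, -40, 0, -5, 1),
      random_cov = rand_cov(55, 1.5, -0.2), residual_sd = 7),
    hippocampus = region_spec("volume",
      beta = c(7.8, -0.01, -0.25, -0.002, -0.35, -0.003, -0.03, 0.005),
      random_cov = rand_cov(0.55, 0.03, -0.2), residual_sd = 0.08),
    midbrain_plane = region_spec("area",
      beta = c(150, -0.2, -6, -0.02, -8, -0.03, -0.4, 0.05),
      random_cov = rand_cov(8, 0.35, -0.1), residual_sd = 1.2),
    caudal_acc = region_spec("thickness",
      beta = c(2.6, -0.004, -0.05, -0.002, -0.07, 0.001, -0.007, 0.002),
      random_cov = rand_cov(0.078, 0.005, -0.1), residual_sd = 0.02),
    superior_frontal = region_spec("thickness",
      beta = c(2.7, -0.005, -0.06, -0.002, -0.08, 0.001, -0.007, 0.002),
      random_cov = rand_cov(0.081, 0.005, -0.1), residual_sd = 0.02),
    precentral = region_spec("thickness",
      beta = c(2.5, -0.004, -0.07, -0.002, -0.09, 0.001, -0.007, 0.002),
      random_cov = rand_cov(0.075, 0.005, -0.1), residual_sd = 0.02),
    posterior_cingulate = region_spec("thickness",
      beta = c(2.45, -0.004, -0.05, -0.002, -0.07, 0.001, -0.007, 0.002),
      random_cov = rand_cov(0.074, 0.005, -0.1), residual_sd = 0.02),
    inferior_parietal = region_spec("thickness",
      beta = c(2.4, -0.004, -0.05, -0.002, -0.07, 0.001, -0.007, 0.002),
      random_cov = rand_cov(0.072, 0.005, -0.1), residual_sd = 0.02)
  )
}

.default_mean_thickness_spec <- function() {
  region_spec("thickness",
    beta = c(2.45, -0.003, -0.03, -0.002, -0.04, 0.001, -0.0073, 0.002),
    random_cov = rand_cov(0.07, 0.004, -0.1), residual_sd = 0.015)
}

#' Configure a synthetic longitudinal cohort
#'
#' The defaults emulate the group sizes, visit schedule, covariate
#' distributions, and cumulative attrition of a multi-center longitudinal PD
#' morphometry study: controls/PD-N/PD-CI of 85/80/92 subjects, visits at
#' 0/1.1/2.4/3.2/3.9 years, cumulative retention taken from the observed
#' per-group drop-out counts, and regional outcomes generated from the
#' 8-parameter fixed-effect design (intercept, time, PD-N indicator,
#' time x PD-N, PD-CI indicator, time x PD-CI, age-above-knot, education) plus
#' per-subject random intercept/slope and residual noise.
#'
#' @param n_per_group Named integer vector `c(CTRL=, PDN=, PDCI=)`.
#' @param visit_times Scheduled visit times in years, strictly increasing,
#'   starting at 0.
#' @param retention Named list (per group) of cumulative retention
#'   probabilities, one per visit, non-increasing, first element 1.
#' @param age_mean_sd Named list (per group) of `c(mean, sd)` for baseline age
#'   (years), truncated to `age_bounds`.
#' @param age_bounds Truncation bounds for baseline age, years.
#' @param education_mean_sd Named list per group, years of education,
#'   truncated to `education_bounds`.
#' @param education_bounds Truncation bounds for education, years.
#' @param sex_prob_male Named vector of per-group male probability.
#' @param icv_mean_sd `c(mean, sd)` for intracranial volume, cm^3.
#' @param regions Named list of region generative specs (see source); each has
#'   `kind`, `beta` (8-vector), `random_cov` (2x2 PSD), `residual_sd`.
#' @param mean_thickness Generative spec for the cortex-wide mean thickness
#'   reference (same structure as a thickness region).
#' @param age_knot Knot (years) of the piecewise age effect.
#' @param age_mode `"enrollment"` (age fixed at baseline in the generative age
#'   term) or `"visit"`.
#' @param visit_jitter Half-width (years) of uniform jitter around scheduled
#'   follow-up times; 0 (default) keeps the exact schedule.
#' @param seed Default seed used by [generate_cohort()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_per_group = c(CTRL = 85, PDN = 80, PDCI = 92),
                             visit_times = c(0, 1.1, 2.4, 3.2, 3.9),
                             retention = NULL,
                             age_mean_sd = list(CTRL = c(65.1, 6.7),
                                                PDN = c(65.9, 8.3),
                                                PDCI = c(68.9, 7.7)),
                             age_bounds = c(45, 80),
                             education_mean_sd = list(CTRL = c(16.1, 4.0),
                                                      PDN = c(13.8, 2.7),
                                                      PDCI = c(13.0, 2.9)),
                             education_bounds = c(7, 30),
                             sex_prob_male = c(CTRL = 48 / 85, PDN = 56 / 80,
                                               PDCI = 64 / 92),
                             icv_mean_sd = c(1459.3, 120),
                             regions = default_region_specs(),
                             mean_thickness = .default_mean_thickness_spec(),
                             age_knot = 60,
                             age_mode = c("enrollment", "visit"),
                             visit_jitter = 0,
                             seed = 1L) {
  age_mode <- match.arg(age_mode)
  if (is.null(retention)) {
    retention <- if (length(visit_times) <= 5L)
      lapply(.DEFAULT_RETENTION, function(r) r[seq_along(visit_times)])
    else
      stats::setNames(rep(list(c(1, rep(0.7, length(visit_times) - 1L))),
                          length(n_per_group)), names(n_per_group))
  }
  cfg <- list(n_per_group = n_per_group, visit_times = visit_times,
              retention = retention, age_mean_sd = age_mean_sd,
              age_bounds = age_bounds, education_mean_sd = education_mean_sd,
              education_bounds = education_bounds,
              sex_prob_male = sex_prob_male, icv_mean_sd = icv_mean_sd,
              regions = regions, mean_thickness = mean_thickness,
              age_knot = age_knot, age_mode = age_mode,
              visit_jitter = visit_jitter, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  vt <- cfg$visit_times
  if (vt[1L] != 0 || any(diff(vt) <= 0))
    lm_error("longmorph_config_error",
             "visit_times must be strictly increasing and start at 0")
  for (g in names(cfg$n_per_group)) {
    r <- cfg$retention[[g]]
    if (is.null(r) || length(r) != length(vt))
      lm_error("longmorph_config_error",
               "retention for group %s must give one probability per visit", g)
    if (r[1L] != 1 || any(diff(r) > 1e-12) || any(r < 0) || any(r > 1))
      lm_error("longmorph_config_error",
               "retention for group %s must be non-increasing in [0, 1]", g)
  }
  specs <- c(cfg$regions, list(.mean_thickness = cfg$mean_thickness))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (length(sp$beta) != 8L)
      lm_error("longmorph_config_error",
               "region %s: beta must have 8 elements", nm)
    rc <- sp$random_cov
    if (!isTRUE(all.equal(rc, t(rc))) || any(eigen(rc, TRUE, TRUE)$values < -1e-10))
      lm_error("longmorph_config_error",
               "region %s: random_cov must be symmetric PSD", nm)
    if (sp$residual_sd < 0)
      lm_error("longmorph_config_error",
               "region %s: residual_sd must be >= 0", nm)
  }
  invisible(cfg)
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mean, sd)
}

# monotone drop-out: present at visit j iff present at j-1 and the
# conditional Bernoulli (cumulative retention ratio) succeeds
draw_last_visit <- function(n, retention) {
  k <- length(retention)
  last <- rep.int(0L, n)
  alive <- rep.int(TRUE, n)
  for (j in seq_len(k - 1L)) {
    cond <- if (retention[j] > 0) retention[j + 1L] / retention[j] else 0
    stay <- alive & (stats::runif(n) < cond)
    last[stay] <- j
    alive <- stay
  }
  last
}

#' Generate a synthetic longitudinal cohort
#'
#' Outcomes follow `y = X beta + b0 + b1 t + e` with the 8-column fixed-effect
#' design (including the knotted age term), subject random effects drawn from
#' the configured 2x2 covariance, and Gaussian residual noise. Drop-out is
#' monotone (a subject absent at one visit is absent at all later visits) and
#' independent of the outcome (missing completely at random). Generated
#' trajectories are produced on the normalized scale and then rescaled by each
#' subject's intracranial volume (volumes, areas) or baseline mean cortical
#' thickness (thickness regions), so that the normalization stage of the
#' pipeline has real work to undo.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; defaults to `config$seed`. The same
#'   `(config, seed)` always yields the identical table.
#' @return A list with elements `table` (a `long_table`) and `truth`
#'   (per-subject realized random effects, drop-out pattern, and the config),
#'   enabling parameter-recovery tests.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  set.seed(seed)
  groups <- names(config$n_per_group)
  subj <- do.call(rbind, lapply(groups, function(g) {
    n <- config$n_per_group[[g]]
    if (n == 0L) return(NULL)
    data.frame(
      subject_id = sprintf("%s%03d", g, seq_len(n)),
      group = g,
      sex = ifelse(stats::runif(n) < config$sex_prob_male[[g]], "M", "F"),
      education = round(rtruncnorm(n, config$education_mean_sd[[g]][1L],
                                   config$education_mean_sd[[g]][2L],
                                   config$education_bounds[1L],
                                   config$education_bounds[2L])),
      baseline_age = rtruncnorm(n, config$age_mean_sd[[g]][1L],
                                config$age_mean_sd[[g]][2L],
                                config$age_bounds[1L], config$age_bounds[2L]),
      icv = pmax(stats::rnorm(n, config$icv_mean_sd[1L], config$icv_mean_sd[2L]),
                 800),
      stringsAsFactors = FALSE)
  }))
  rownames(subj) <- NULL
  n_subj <- nrow(subj)
  subj$last_visit <- unlist(lapply(groups, function(g)
    draw_last_visit(config$n_per_group[[g]], config$retention[[g]])))

  # per-subject visit rows
  visit_rows <- lapply(seq_len(n_subj), function(i) {
    vi <- 0:subj$last_visit[i]
    tt <- config$visit_times[vi + 1L]
    if (config$visit_jitter > 0 && length(vi) > 1L)
      tt[-1L] <- tt[-1L] + stats::runif(length(vi) - 1L,
                                        -config$visit_jitter,
                                        config$visit_jitter)
    data.frame(subject_id = subj$subject_id[i], visit_index = vi,
               time_from_baseline = tt, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, visit_rows)
  si <- match(d$subject_id, subj$subject_id)
  for (col in c("group", "sex", "education", "baseline_age", "icv"))
    d[[col]] <- subj[[col]][si]
  d$age_at_visit <- d$baseline_age + d$time_from_baseline
  d$cognitive_status <- ifelse(d$group == "PDCI", "MCI", "NORMAL")
  d$converter_label <- NA_character_

  # fixed-effect design rows for the generative model
  age_gen <- if (config$age_mode == "enrollment") d$baseline_age else
    d$age_at_visit
  X <- cbind(1, d$time_from_baseline,
             as.numeric(d$group == "PDN"),
             d$time_from_baseline * (d$group == "PDN"),
             as.numeric(d$group == "PDCI"),
             d$time_from_baseline * (d$group == "PDCI"),
             pmax(age_gen - config$age_knot, 0),
             d$education)

  specs <- c(config$regions, list(mean_thickness = config$mean_thickness))
  ranef <- list()
  norm_values <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    L <- chol_psd(sp$random_cov)
    b <- matrix(stats::rnorm(2L * n_subj), n_subj, 2L) %*% t(L)
    idx <- match(d$subject_id, subj$subject_id)
    y <- drop(X %*% sp$beta) + b[idx, 1L] + b[idx, 2L] * d$time_from_baseline +
      stats::rnorm(nrow(d), 0, sp$residual_sd)
    ranef[[nm]] <- data.frame(subject_id = subj$subject_id,
                              b_intercept = b[, 1L], b_slope = b[, 2L],
                              stringsAsFactors = FALSE)
    norm_values[[nm]] <- y
  }

  # rescale from the normalized to the raw scale
  icv_mean <- mean(subj$icv)
  mt_norm <- norm_values$mean_thickness
  d$mean_thickness <- mt_norm  # reference itself is stored as generated
  mt_baseline <- mt_norm[d$visit_index == 0L][match(d$subject_id,
                                                    d$subject_id[d$visit_index == 0L])]
  mt_mean <- mean(mt_norm[d$visit_index == 0L])
  for (nm in names(config$regions)) {
    sp <- config$regions[[nm]]
    if (sp$kind == "thickness") {
      d[[nm]] <- norm_values[[nm]] * mt_baseline / mt_mean
    } else {
      d[[nm]] <- norm_values[[nm]] * d$icv / icv_mean
    }
  }

  reg <- region_dictionary(names(config$regions),
                           vapply(config$regions, `[[`, "", "kind"),
                           vapply(config$regions, `[[`, "", "units"))
  table <- long_table(d, reg)
  truth <- list(config = config, seed = seed, subjects = subj,
                random_effects = ranef)
  list(table = table, truth = truth)
}

# Cholesky-like factor that tolerates PSD (zero-variance) matrices
chol_psd <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), nrow = length(v)) %*% t(e$vectors)
}

#' Generate a converter-comparison scenario
#'
#' Splits the cognitively normal PD arm into future converters (cPDN) and
#' nonconverters (nPDN), plants a baseline thickness deficit (e.g. -3%) in one
#' thickness region of the converter arm, makes the cognitive-status
#' trajectories consistent with the labels (converters acquire MCI from a
#' configurable visit onwards), and optionally plants a monotone association
#' between the thinned region and a per-subject cognitive score. PD-N
#' retention is forced to 1 at the first follow-up so every PD-N subject is
#' labelable, mirroring the observed converter-cohort attrition.
#'
#' @param config A [synthetic_config()].
#' @param thinning_region Name of a thickness-kind region in the dictionary.
#' @param thinning_delta Fractional baseline shift in `[-0.2, 0]`, e.g. -0.03
#'   for a 3% thinning.
#' @param converter_fraction Probability that a PD-N subject is a converter
#'   (default 26/68, the observed fraction).
#' @param conversion_visit First visit index at which converters are MCI.
#' @param score_rho Target correlation between the planted region's baseline
#'   value and the generated `cognitive_score` column across PD-N subjects
#'   (set to 0 to disable the association; scores are generated either way).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with `table` (a `long_table`, including a subject-level
#'   `cognitive_score` column for PD-N subjects) and `truth` (including the
#'   planted arm assignment in `truth$arms`).
#' @export
generate_converter_scenario <- function(config, thinning_region,
                                        thinning_delta,
                                        converter_fraction = 26 / 68,
                                        conversion_visit = 1L,
                                        score_rho = 0.4,
                                        seed = config$seed) {
  if (!thinning_region %in% names(config$regions))
    lm_error("longmorph_config_error", "region '%s' not in the dictionary",
             thinning_region)
  if (config$regions[[thinning_region]]$kind != "thickness")
    lm_error("longmorph_config_error",
             "thinning region must be thickness-kind")
  if (thinning_delta < -0.2 || thinning_delta > 0)
    lm_error("longmorph_config_error", "thinning_delta must lie in [-0.2, 0]")
  # PD-N retention: complete first follow-up, then the observed converter-arm
  # cumulative retention (pooled nPDN/cPDN counts 68 -> 68/28/18/6)
  config$retention$PDN <- c(1, 1, 28 / 68, 18 / 68, 6 / 68)[
    seq_along(config$visit_times)]
  gen <- generate_cohort(config, seed = seed)
  d <- gen$table$data
  pdn_ids <- unique(d$subject_id[d$group == "PDN"])
  arm <- ifelse(stats::runif(length(pdn_ids)) < converter_fraction,
                "cPDN", "nPDN")
  names(arm) <- pdn_ids

  is_c <- d$subject_id %in% pdn_ids[arm == "cPDN"]
  d[[thinning_region]][is_c] <- d[[thinning_region]][is_c] * (1 + thinning_delta)
  conv <- is_c & d$visit_index >= conversion_visit
  d$cognitive_status[conv] <- "MCI"

  # subject-level cognitive score with a planted monotone association to the
  # planted region's baseline value (PD-N subjects only)
  base <- d[d$visit_index == 0L & d$group == "PDN", , drop = FALSE]
  z <- as.numeric(scale(base[[thinning_region]]))
  e <- stats::rnorm(length(z))
  score <- 95 + 6 * (score_rho * z + sqrt(max(1 - score_rho^2, 0)) * e)
  d$cognitive_score <- score[match(d$subject_id, base$subject_id)]

  table <- long_table(d, gen$table$regions)
  truth <- gen$truth
  truth$arms <- data.frame(subject_id = pdn_ids, arm = unname(arm),
                           stringsAsFactors = FALSE)
  truth$thinning <- list(region = thinning_region, delta = thinning_delta,
                         conversion_visit = conversion_visit,
                         score_rho = score_rho)
  list(table = table, truth = truth)
}
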