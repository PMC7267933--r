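# Reference normalization and control-derived covariate correction.
#
# Regional volumes (and planar areas) are normalized to the study-mean
# intracranial volume, v_norm = v / ICV_i * mean(ICV); regional cortical
# thickness values are normalized the same way with the subject's mean
# cortical thickness as the reference. Normalized values are then corrected
# for age and years of education using per-region slopes estimated by
# ordinary least squares from the baseline records of the healthy controls,
# and re-centered at the whole-study baseline mean age and education.

#' Normalization reference
#'
#' @param kind `"ICV"` (volumes, areas) or `"MEAN_THICKNESS"` (thickness).
#' @param cohort_mean Arithmetic mean of the per-subject reference over the
#'   baseline whole study population; must be positive.
#' @return A `normalization_reference` object.
#' @export
normalization_reference <- function(kind = c("ICV", "MEAN_THICKNESS"),
                                    cohort_mean) {
  kind <- match.arg(kind)
  if (!is.finite(cohort_mean) || cohort_mean <= 0)
    lm_error("longmorph_domain_error", "cohort_mean must be positive")
  structure(list(kind = kind, cohort_mean = cohort_mean),
            class = "normalization_reference")
}

#' Compute a normalization reference from a cohort table
#'
#' The cohort mean is the arithmetic mean over baseline visits of the whole
#' study population: intracranial volume for `"ICV"`, the `mean_thickness`
#' column for `"MEAN_THICKNESS"`.
#'
#' @param table A `long_table`.
#' @param kind Reference kind.
#' @return A [normalization_reference()].
#' @export
compute_reference <- function(table, kind = c("ICV", "MEAN_THICKNESS")) {
  kind <- match.arg(kind)
  b <- baseline_slice(table)$data
  v <- if (kind == "ICV") b$icv else b$mean_thickness
  if (all(is.na(v)))
    lm_error("longmorph_domain_error",
             "no baseline reference values available for %s", kind)
  normalization_reference(kind, mean(v, na.rm = TRUE))
}

#' Normalize a measurement to a cohort reference
#'
#' Computes `value * cohort_mean / subject_reference`; units are preserved
#' (the subject reference and the cohort mean share units, so their ratio is
#' dimensionless).
#'
#' @param value Measurement(s) to normalize.
#' @param subject_reference The subject's own reference value (e.g. their
#'   intracranial volume in cm^3); must be positive.
#' @param reference A [normalization_reference()].
#' @return Normalized measurement(s).
#' @export
normalize_to_reference <- function(value, subject_reference, reference) {
  stopifnot(inherits(reference, "normalization_reference"))
  if (any(!is.finite(subject_reference) | subject_reference <= 0))
    lm_error("longmorph_domain_error", "subject reference must be positive")
  value * reference$cohort_mean / subject_reference
}

#' Normalize all region columns of a cohort table
#'
#' Volume and area regions are normalized to the cohort-mean intracranial
#' volume using each subject's (time-constant, baseline) ICV; thickness
#' regions to the cohort-mean of baseline mean cortical thickness using each
#' subject's baseline mean thickness. A provenance flag prevents accidental
#' double normalization.
#'
#' @param table A `long_table`.
#' @return The table with region columns normalized and provenance updated.
#' @export
normalize_table <- function(table) {
  stopifnot(inherits(table, "long_table"))
  if ("normalized" %in% table$provenance)
    lm_error("longmorph_integrity_error", "table is already normalized")
  d <- table$data
  base <- d[d$visit_index == 0L, , drop = FALSE]
  ref_icv <- normalization_reference("ICV", mean(base$icv))
  has_thk <- any(table$regions$kind == "thickness")
  if (has_thk) {
    if (all(is.na(base$mean_thickness)))
      lm_error("longmorph_domain_error",
               "thickness regions present but mean_thickness is all missing")
    ref_mt <- normalization_reference("MEAN_THICKNESS",
                                      mean(base$mean_thickness, na.rm = TRUE))
    mt_subj <- base$mean_thickness[match(d$subject_id, base$subject_id)]
  }
  for (i in seq_len(nrow(table$regions))) {
    r <- table$regions$region[i]
    if (table$regions$kind[i] == "thickness") {
      d[[r]] <- normalize_to_reference(d[[r]], mt_subj, ref_mt)
    } else {
      d[[r]] <- normalize_to_reference(d[[r]], d$icv, ref_icv)
    }
  }
  table$data <- d
  table$provenance <- c(table$provenance, "normalized")
  table
}

#' Fit the control-derived covariate correction model for one region
#'
#' Ordinary least-squares fit of the three-parameter linear model
#' `v_norm = g0 + g1 * age + g2 * education` (optionally plus a sex indicator)
#' on baseline records of healthy controls only. The reference covariates at
#' which corrected values are re-centered are the baseline means of the whole
#' study population, supplied by the caller (they default to the means of the
#' fitting slice, which is only correct when the slice is the whole study
#' population).
#'
#' @param controls_baseline A `long_table` slice: baseline visits of the
#'   control group, with `region` already normalized.
#' @param region Region column to fit.
#' @param x_age_ref,x_edu_ref Reference age and education (years) for
#'   re-centering; whole-study baseline means.
#' @param include_sex Add a male-indicator covariate (used for mean cortical
#'   thickness analyses).
#' @param sex_ref Reference male proportion for re-centering when
#'   `include_sex` is `TRUE`.
#' @return A `covariate_model` with slopes `gamma` and fit diagnostics.
#' @export
fit_control_covariate_model <- function(controls_baseline, region,
                                        x_age_ref = NULL, x_edu_ref = NULL,
                                        include_sex = FALSE, sex_ref = NULL) {
  stopifnot(inherits(controls_baseline, "long_table"))
  d <- controls_baseline$data
  d <- d[d$visit_index == 0L & d$group == "CTRL" & !is.na(d[[region]]), ,
         drop = FALSE]
  if (nrow(d) < 3L)
    lm_error("longmorph_singular_error",
             "need >= 3 baseline control records to fit the covariate model")
  if (is.null(x_age_ref)) x_age_ref <- mean(d$baseline_age)
  if (is.null(x_edu_ref)) x_edu_ref <- mean(d$education)
  df <- data.frame(y = d[[region]], age = d$baseline_age, edu = d$education,
                   male = as.numeric(d$sex == "M"))
  form <- if (include_sex) y ~ age + edu + male else y ~ age + edu
  X <- stats::model.matrix(form, df)
  if (qr(X)$rank < ncol(X))
    lm_error("longmorph_singular_error",
             "rank-deficient covariate design (no variation in age/education)")
  fit <- stats::lm(form, data = df)
  if (include_sex && is.null(sex_ref)) sex_ref <- mean(df$male)
  structure(list(region = region,
                 gamma = stats::coef(fit),
                 x_age_ref = x_age_ref, x_edu_ref = x_edu_ref,
                 include_sex = include_sex, sex_ref = sex_ref,
                 n = nrow(d), residual_sd = stats::sigma(fit)),
            class = "covariate_model")
}

#' Apply the covariate correction to normalized measurements
#'
#' Computes `value - g1 * (age - age_ref) - g2 * (education - edu_ref)`
#' (minus the centered sex term when the model includes one). A subject whose
#' covariates equal the reference values is unchanged.
#'
#' @param value Normalized measurement(s).
#' @param age Age(s) in years at which to correct.
#' @param education Years of education.
#' @param model A `covariate_model` from [fit_control_covariate_model()].
#' @param sex Optional sex value(s) (`"M"`/`"F"` or 0/1 male indicator),
#'   required when the model includes a sex term.
#' @return Corrected measurement(s).
#' @export
apply_covariate_correction <- function(value, age, education, model,
                                       sex = NULL) {
  stopifnot(inherits(model, "covariate_model"))
  g <- model$gamma
  out <- value - g[["age"]] * (age - model$x_age_ref) -
    g[["edu"]] * (education - model$x_edu_ref)
  if (model$include_sex) {
    if (is.null(sex))
      lm_error("longmorph_domain_error",
               "model includes a sex term; supply sex")
    male <- if (is.character(sex)) as.numeric(sex == "M") else as.numeric(sex)
    out <- out - g[["male"]] * (male - model$sex_ref)
  }
  out
}

#' Correct all region columns of a normalized table
#'
#' Fits one control-derived covariate model per region and applies it to all
#' rows. The correction age is by default the age at the visit being
#' corrected; `age_mode = "baseline"` uses enrollment age throughout. A
#' provenance flag enforces single application.
#'
#' @param table A normalized `long_table`.
#' @param age_mode `"visit"` (default) or `"baseline"`.
#' @param sex_regions Character vector of regions whose model additionally
#'   includes a sex indicator (conventionally only cortex-wide mean
#'   thickness).
#' @return A list with `table` (corrected) and `models` (per-region
#'   `covariate_model`s).
#' @export
correct_table <- function(table, age_mode = c("visit", "baseline"),
                          sex_regions = character()) {
  stopifnot(inherits(table, "long_table"))
  age_mode <- match.arg(age_mode)
  if (!"normalized" %in% table$provenance)
    lm_error("longmorph_integrity_error",
             "correct_table expects a normalized table")
  if ("corrected" %in% table$provenance)
    lm_error("longmorph_integrity_error", "table is already corrected")
  d <- table$data
  base <- d[d$visit_index == 0L, , drop = FALSE]
  x_age_ref <- mean(base$baseline_age)
  x_edu_ref <- mean(base$education)
  age <- if (age_mode == "visit") d$age_at_visit else d$baseline_age
  models <- list()
  for (r in table$regions$region) {
    m <- fit_control_covariate_model(table, r, x_age_ref = x_age_ref,
                                     x_edu_ref = x_edu_ref,
                                     include_sex = r %in% sex_regions)
    d[[r]] <- apply_covariate_correction(d[[r]], age, d$education, m,
                                         sex = if (m$include_sex) d$sex)
    models[[r]] <- m
  }
  table$data <- d
  table$provenance <- c(table$provenance, "corrected")
  list(table = table, models = models)
}

#' Average left/right hemisphere measurements
#'
#' Takes a named vector of per-hemisphere values (region names carrying a
#' left/right suffix) and returns the unweighted arithmetic mean per bilateral
#' region. Regions with only one hemisphere present yield a missing value and
#' a warning.
#'
#' @param values Named numeric vector, names like `region_lh` / `region_rh`.
#' @param left_suffix,right_suffix Hemisphere suffixes.
#' @return Named numeric vector of per-region means.
#' @export
hemisphere_average <- function(values, left_suffix = "_lh",
                               right_suffix = "_rh") {
  nm <- names(values)
  is_l <- endsWith(nm, left_suffix)
  is_r <- endsWith(nm, right_suffix)
  base_l <- substr(nm[is_l], 1L, nchar(nm[is_l]) - nchar(left_suffix))
  base_r <- substr(nm[is_r], 1L, nchar(nm[is_r]) - nchar(right_suffix))
  regions <- sort(unique(c(base_l, base_r)))
  out <- stats::setNames(rep(NA_real_, length(regions)), regions)
  for (r in regions) {
    l <- values[paste0(r, left_suffix)]
    rg <- values[paste0(r, right_suffix)]
    if (is.na(l) || is.na(rg)) {
      warning(sprintf("region '%s': missing one hemisphere, result is NA", r),
              call. = FALSE)
      next
    }
    out[r] <- (l + rg) / 2
  }
  out
}

#' Percent deviation of a group mean from the control mean
#'
#' `(group_mean / control_mean - 1) * 100`; negative values indicate loss
#' (atrophy), positive values indicate e-vacuo gain (as for CSF spaces).
#'
#' @param group_mean Group mean measurement.
#' @param control_mean Control mean measurement; must be nonzero.
#' @return Signed percentage.
#' @export
percent_deviation <- function(group_mean, control_mean) {
  if (any(control_mean == 0))
    lm_error("longmorph_domain_error", "control mean must be nonzero")
  (group_mean / control_mean - 1) * 100
}
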