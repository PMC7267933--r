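# Orchestration of the three analyses over a cohort table:
#   run_baseline      - atrophy distribution at study entry (per-region
#                       normalized, covariate-corrected group means, percent
#                       deviation vs controls, Welch t with a Lilliefors
#                       normality gate, Bonferroni flags)
#   run_longitudinal  - per-region REML mixed-model atrophy rates with the
#                       slope-equality contrast F-test and exploratory LOWESS
#                       group trajectories
#   run_converters    - baseline comparison of future MCI converters vs
#                       nonconverters vs controls (Kruskal-Wallis omnibus,
#                       gated post hoc Welch t pairs, score correlation)

#' Run configuration
#'
#' @param knot Age knot in years for the mixed model.
#' @param age_mode Age covariate mode for the mixed model (`"enrollment"` or
#'   `"visit"`).
#' @param correction_age_mode Age used by the covariate correction (`"visit"`
#'   or `"baseline"`).
#' @param df_method Denominator-degrees-of-freedom method for contrast
#'   F-tests.
#' @param alpha Significance level.
#' @param m Bonferroni family size override; default: number of tests in the
#'   report.
#' @param sex_regions Regions whose covariate correction includes sex.
#' @param lilliefors_n_mc Monte-Carlo replicates for the normality gate.
#' @param seed Seed for the Monte-Carlo normality gate.
#' @return A `run_config` list.
#' @export
run_config <- function(knot = 60, age_mode = c("enrollment", "visit"),
                       correction_age_mode = c("visit", "baseline"),
                       df_method = c("residual", "satterthwaite"),
                       alpha = 0.05, m = NULL,
                       sex_regions = character(),
                       lilliefors_n_mc = 1000L, seed = 1L) {
  if (alpha <= 0 || alpha >= 1)
    lm_error("longmorph_config_error", "alpha must lie in (0, 1)")
  structure(list(knot = knot, age_mode = match.arg(age_mode),
                 correction_age_mode = match.arg(correction_age_mode),
                 df_method = match.arg(df_method), alpha = alpha, m = m,
                 sex_regions = sex_regions,
                 lilliefors_n_mc = as.integer(lilliefors_n_mc),
                 seed = as.integer(seed)),
            class = "run_config")
}

group_values <- function(d, region, group)
  d[[region]][d$group == group & !is.na(d[[region]])]

#' Baseline atrophy-distribution report
#'
#' Per region: ICV/mean-thickness normalization, control-derived age and
#' education correction, a Lilliefors normality gate (regions that fail switch
#' from Welch t to Kruskal-Wallis for the group comparison), percent deviation
#' of each patient group's corrected mean from controls, and Bonferroni flags
#' across all tests in the report.
#'
#' @param table A raw `long_table` with baseline visits for all groups.
#' @param config A [run_config()].
#' @return A `data.frame` with one row per (region, patient group).
#' @export
run_baseline <- function(table, config = run_config()) {
  stopifnot(inherits(table, "long_table"))
  base <- baseline_slice(table)
  counts <- table(base$data$group)
  if (any(!c("CTRL") %in% names(counts)) || any(counts < 2))
    lm_error("longmorph_domain_error",
             "every group needs >= 2 baseline records (have: %s)",
             paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  norm <- normalize_table(base)
  corr <- correct_table(norm, age_mode = config$correction_age_mode,
                        sex_regions = config$sex_regions)
  d <- corr$table$data
  patient_groups <- intersect(c("PDN", "PDCI"), unique(d$group))
  rows <- list()
  set.seed(config$seed)
  for (i in seq_len(nrow(table$regions))) {
    r <- table$regions$region[i]
    ctrl <- group_values(d, r, "CTRL")
    lil <- lilliefors(d[[r]][!is.na(d[[r]])], n_mc = config$lilliefors_n_mc)
    normal_ok <- lil$p >= config$alpha
    for (g in patient_groups) {
      v <- group_values(d, r, g)
      ht <- if (normal_ok) welch_t(v, ctrl) else
        kruskal_wallis(list(v, ctrl))
      rows[[length(rows) + 1L]] <- data.frame(
        region = r, kind = table$regions$kind[i], group = g,
        n = length(v), n_ctrl = length(ctrl),
        corrected_mean = mean(v), control_mean = mean(ctrl),
        delta_pct = percent_deviation(mean(v), mean(ctrl)),
        test = ht$method, statistic = ht$statistic, p = ht$p,
        lilliefors_p = lil$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- if (is.null(config$m)) nrow(out) else config$m
  bf <- bonferroni(out$p, m = m, alpha = config$alpha)
  out$p_bonferroni <- bf$adjusted
  out$significant <- bf$significant
  attr(out, "bonferroni_m") <- m
  rownames(out) <- NULL
  out
}

#' Longitudinal atrophy-rate report
#'
#' Per region: reference normalization, the 8-column mixed-model design with
#' the knotted age term, REML fit with random intercept and slope, and the
#' slope-equality contrast F-test (DF1 = 2). Exploratory LOWESS group
#' trajectories are returned alongside. Regions whose fit fails are collected
#' as errors without aborting the run.
#'
#' @param table A raw `long_table` with repeated visits.
#' @param config A [run_config()].
#' @param lowess Also compute per-group LOWESS trajectories
#'   (time vs normalized value).
#' @return List with `report` (a [slope_table()] data.frame), `fits`,
#'   `lowess` (per region, per group `lowess_curve`s), and `errors`.
#' @export
run_longitudinal <- function(table, config = run_config(), lowess = FALSE) {
  stopifnot(inherits(table, "long_table"))
  norm <- normalize_table(table)
  d <- norm$data
  fits <- list()
  errors <- list()
  curves <- list()
  for (i in seq_len(nrow(table$regions))) {
    r <- table$regions$region[i]
    res <- tryCatch({
      des <- build_design(norm, r, knot = config$knot,
                          age_mode = config$age_mode)
      fit_lme(des)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[r]] <- conditionMessage(res)
    } else {
      fits[[r]] <- res
    }
    if (lowess) {
      curves[[r]] <- lapply(stats::setNames(nm = unique(d$group)), function(g) {
        keep <- d$group == g & !is.na(d[[r]])
        if (sum(keep) < 5L) return(NULL)
        lowess_fit(d$time_from_baseline[keep], d[[r]][keep])
      })
    }
  }
  kinds <- stats::setNames(table$regions$kind, table$regions$region)
  report <- if (length(fits) > 0L)
    slope_table(fits, region_kinds = kinds, df_method = config$df_method,
                alpha = config$alpha)
  else NULL
  list(report = report, fits = fits, lowess = curves, errors = errors)
}

#' Converter-comparison report
#'
#' Baseline-only comparison of thickness regions across controls,
#' nonconverters (nPDN) and converters (cPDN): per region a Kruskal-Wallis
#' omnibus, post hoc Welch t pairs when the omnibus is significant, the
#' percent deviation between converter arms, and a Spearman correlation of
#' the pooled PD-N values against a cognitive score column. Follow-up visits
#' are used only to assign the converter labels.
#'
#' @param table A raw `long_table` with per-visit cognitive status.
#' @param config A [run_config()].
#' @param score_column Optional name of a subject-level score column for the
#'   correlation stage (e.g. a composite cognitive score).
#' @param regions Regions to compare; default all thickness-kind regions.
#' @return A `data.frame` with one row per region, plus attributes
#'   `bonferroni_m` and per-region correlation columns.
#' @export
run_converters <- function(table, config = run_config(), score_column = NULL,
                           regions = NULL) {
  stopifnot(inherits(table, "long_table"))
  table <- label_converters(table)
  if (is.null(regions))
    regions <- table$regions$region[table$regions$kind == "thickness"]
  base <- baseline_slice(table)
  norm <- normalize_table(base)
  corr <- correct_table(norm, age_mode = config$correction_age_mode,
                        sex_regions = config$sex_regions)
  d <- corr$table$data
  arm <- ifelse(d$group == "CTRL", "CTRL", d$converter_label)
  usable <- !is.na(arm)
  if (!all(c("CTRL", "nPDN", "cPDN") %in% unique(arm[usable])))
    lm_error("longmorph_domain_error",
             "need non-empty CTRL, nPDN and cPDN arms")
  rows <- list()
  for (r in regions) {
    ok <- usable & !is.na(d[[r]])
    vals <- split(d[[r]][ok], arm[ok])[c("CTRL", "nPDN", "cPDN")]
    omni <- kruskal_wallis(vals)
    row <- data.frame(region = r,
                      n_ctrl = length(vals$CTRL), n_npdn = length(vals$nPDN),
                      n_cpdn = length(vals$cPDN),
                      mean_ctrl = mean(vals$CTRL),
                      mean_npdn = mean(vals$nPDN),
                      mean_cpdn = mean(vals$cPDN),
                      delta_pct_cpdn_vs_npdn =
                        percent_deviation(mean(vals$cPDN), mean(vals$nPDN)),
                      chi2 = omni$statistic, omnibus_p = omni$p,
                      t_cpdn_npdn = NA_real_, p_cpdn_npdn = NA_real_,
                      t_cpdn_ctrl = NA_real_, p_cpdn_ctrl = NA_real_,
                      t_npdn_ctrl = NA_real_, p_npdn_ctrl = NA_real_,
                      score_rho = NA_real_, score_p = NA_real_,
                      stringsAsFactors = FALSE)
    if (omni$p < config$alpha) {
      # post hoc unpaired t tests, gated on the omnibus
      ph1 <- welch_t(vals$cPDN, vals$nPDN)
      ph2 <- welch_t(vals$cPDN, vals$CTRL)
      ph3 <- welch_t(vals$nPDN, vals$CTRL)
      row$t_cpdn_npdn <- ph1$statistic; row$p_cpdn_npdn <- ph1$p
      row$t_cpdn_ctrl <- ph2$statistic; row$p_cpdn_ctrl <- ph2$p
      row$t_npdn_ctrl <- ph3$statistic; row$p_npdn_ctrl <- ph3$p
    }
    if (!is.null(score_column) && score_column %in% names(d)) {
      pdn <- d$group == "PDN" & !is.na(d$converter_label) & !is.na(d[[r]]) &
        !is.na(d[[score_column]])
      if (sum(pdn) >= 3L) {
        sc <- spearman(d[[r]][pdn], d[[score_column]][pdn])
        row$score_rho <- sc$statistic
        row$score_p <- sc$p
      }
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  m <- if (is.null(config$m)) nrow(out) else config$m
  bf <- bonferroni(out$omnibus_p, m = m, alpha = config$alpha)
  out$omnibus_p_bonferroni <- bf$adjusted
  out$omnibus_significant <- bf$significant
  # a region is flagged as a converter effect when the omnibus fires and the
  # cPDN-vs-nPDN post hoc is itself significant
  out$converter_flag <- out$omnibus_p < config$alpha &
    !is.na(out$p_cpdn_npdn) & out$p_cpdn_npdn < config$alpha
  attr(out, "bonferroni_m") <- m
  out
}
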