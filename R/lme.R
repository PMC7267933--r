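# Linear mixed-effect model of regional atrophy rates.
#
# Fixed-effect design (8 columns, fixed order): intercept, time from baseline
# t, PD-N indicator G1, t*G1, PD-CI indicator G2, t*G2, piecewise-transformed
# age (years above the knot), years of education. Controls are the reference
# group, so the per-group atrophy slopes are beta_time (controls),
# beta_time + beta_time:PDN (PD-N) and beta_time + beta_time:PDCI (PD-CI).
# Random effects: per-subject intercept and slope with unstructured 2x2
# covariance (compound symmetry not assumed). Estimation is REML: the
# relative random-effects covariance G = Psi / sigma^2 is parametrized by a
# log-Cholesky factor and optimized by Nelder-Mead from a method-of-moments
# start; beta is generalized least squares at the optimum, and sigma^2 is
# profiled out. Group-slope equality is tested with a contrast F statistic.

.FIXED_NAMES <- c("(Intercept)", "time", "PDN", "time:PDN", "PDCI",
                  "time:PDCI", "age_over_knot", "education")

#' Piecewise (knotted) age transform
#'
#' Age effects on brain volume and thickness are taken as negligible below
#' the knot and linear above it: `(age - knot) * H(age - knot)` with the
#' Heaviside step `H(x) = 1` for `x > 0` and 0 otherwise (so the transform is
#' exactly 0 at the knot).
#'
#' @param age Age(s) in years.
#' @param knot Knot location in years, within \[40, 80\]; default 60.
#' @return Years above the knot (0 at or below it).
#' @examples
#' piecewise_age(c(50, 60, 70)) # 0, 0, 10
#' @export
piecewise_age <- function(age, knot = 60) {
  if (knot < 40 || knot > 80)
    lm_error("longmorph_config_error", "knot must lie in [40, 80]")
  pmax(age - knot, 0)
}

#' Build the mixed-model design for one region
#'
#' Assembles the aligned fixed-effect matrix `X` (8 columns, fixed order),
#' random-effect matrix `Z` (intercept, time), and outcome vector `y` from a
#' normalized cohort table. Rows with missing outcome are dropped
#' (complete-case per region). Group membership is taken from the frozen
#' baseline group label.
#'
#' @param table A normalized `long_table`.
#' @param region Region column to model.
#' @param knot Age knot in years.
#' @param age_mode `"enrollment"` (default: age at study entry, constant per
#'   subject, passed through the knot transform) or `"visit"` (age at each
#'   measurement).
#' @return An `lme_design` with elements `X`, `Z`, `y`, `subject`, and
#'   bookkeeping fields.
#' @export
build_design <- function(table, region, knot = 60,
                         age_mode = c("enrollment", "visit")) {
  stopifnot(inherits(table, "long_table"))
  age_mode <- match.arg(age_mode)
  d <- table$data
  if (!region %in% names(d))
    lm_error("longmorph_schema_error", "region '%s' not in table", region)
  keep <- !is.na(d[[region]])
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L)
    lm_error("longmorph_domain_error", "no non-missing outcome for region %s",
             region)
  if (any(is.na(d$group)))
    lm_error("longmorph_domain_error", "subject with unknown group")
  t <- d$time_from_baseline
  age <- if (age_mode == "enrollment") d$baseline_age else d$age_at_visit
  X <- cbind(1, t,
             as.numeric(d$group == "PDN"), t * (d$group == "PDN"),
             as.numeric(d$group == "PDCI"), t * (d$group == "PDCI"),
             piecewise_age(age, knot), d$education)
  colnames(X) <- .FIXED_NAMES
  structure(list(X = X, Z = cbind(1, t), y = d[[region]],
                 subject = d$subject_id, time = t, region = region,
                 knot = knot, age_mode = age_mode,
                 n_obs = nrow(d), n_subjects = length(unique(d$subject_id))),
            class = "lme_design")
}

# --- internal REML machinery -------------------------------------------------

# Subjects sharing an identical time vector share the marginal correlation
# structure Sigma_i = I + Z_i G Z_i'; group them into patterns so each
# objective evaluation does one small Cholesky per pattern plus blocked
# matrix products over all subjects of that pattern.
build_patterns <- function(design) {
  idx_by_subj <- split(seq_len(design$n_obs), design$subject)
  keys <- vapply(idx_by_subj, function(ix)
    paste(sprintf("%.10f", design$time[ix]), collapse = ","), "")
  patterns <- lapply(split(idx_by_subj, keys), function(subjs) {
    m <- length(subjs[[1L]])
    ns <- length(subjs)
    ix <- unlist(subjs)               # subject-major, m rows each
    Xl <- design$X[ix, , drop = FALSE]
    list(m = m, ns = ns, t = design$time[subjs[[1L]]],
         Xlong = Xl,                       # (ns*m) x p, subject-major rows
         Ym = matrix(design$y[ix], nrow = m),
         Xarr = aperm(array(t(Xl), c(ncol(Xl), m, ns)), c(2L, 1L, 3L)))
  })
  patterns
}

# profiled -2 REML log-likelihood and GLS quantities for relative covariance G
reml_eval <- function(patterns, G, p, n_obs, want_beta = FALSE) {
  XtWX <- matrix(0, p, p)
  XtWy <- numeric(p)
  ytWy <- 0
  logdet <- 0
  for (pat in patterns) {
    m <- pat$m
    Zi <- cbind(1, pat$t)
    Sigma <- diag(m) + Zi %*% G %*% t(Zi)
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    logdet <- logdet + 2 * pat$ns * sum(log(diag(R)))
    P <- chol2inv(R)                      # m x m
    # blocked products over all subjects of this pattern
    Xm <- matrix(aperm(pat$Xarr, c(1L, 3L, 2L)), nrow = m)   # m x (ns*p)
    PX <- P %*% Xm                                            # m x (ns*p)
    PXlong <- matrix(array(PX, c(m, pat$ns, p)), nrow = m * pat$ns) # (ns*m) x p
    XtWX <- XtWX + crossprod(pat$Xlong, PXlong)
    PY <- P %*% pat$Ym                                        # m x ns
    XtWy <- XtWy + drop(crossprod(PXlong, as.vector(pat$Ym)))
    ytWy <- ytWy + sum(pat$Ym * PY)
  }
  Rx <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(Rx)) return(NULL)
  beta <- backsolve(Rx, forwardsolve(t(Rx), XtWy))
  rss <- ytWy - sum(XtWy * beta)
  if (rss <= 0) return(NULL)
  sigma2 <- rss / (n_obs - p)
  obj <- logdet + 2 * sum(log(diag(Rx))) +
    (n_obs - p) * (1 + log(2 * pi * sigma2))
  if (!want_beta) return(obj)
  list(objective = obj, beta = beta, sigma2 = sigma2,
       cov_beta = sigma2 * chol2inv(Rx))
}

theta_to_G <- function(theta) {
  # clamp the log-Cholesky parameters: variance ratios outside
  # [exp(-30), exp(30)] are numerically indistinguishable from the boundary
  # (the REML surface is flat along such ridges, e.g. with one visit per
  # subject) and would otherwise overflow
  theta <- pmin(pmax(theta, -15), 15)
  if (length(theta) == 1L) return(matrix(exp(2 * theta), 1L, 1L))
  L <- matrix(c(exp(theta[1L]), theta[2L], 0, exp(theta[3L])), 2L, 2L)
  L %*% t(L)
}

# method-of-moments start from per-subject OLS lines
mom_start <- function(design, random) {
  idx_by_subj <- split(seq_len(design$n_obs), design$subject)
  coefs <- NULL
  resid2 <- c()
  for (ix in idx_by_subj) {
    tt <- design$time[ix]
    if (length(unique(tt)) >= 2L) {
      f <- stats::lm.fit(cbind(1, tt), design$y[ix])
      coefs <- rbind(coefs, f$coefficients)
      if (length(ix) > 2L) resid2 <- c(resid2, f$residuals^2)
    }
  }
  sigma2 <- if (length(resid2) > 3L) sum(resid2) / length(resid2) else
    stats::var(design$y) / 4
  sigma2 <- max(sigma2, 1e-8 * stats::var(design$y), .Machine$double.eps)
  if (random == "intercept") {
    v0 <- if (!is.null(coefs)) max(stats::var(coefs[, 1L]) / sigma2, 1e-2) else 1
    return(log(sqrt(v0)))
  }
  if (is.null(coefs) || nrow(coefs) < 3L) return(c(0, 0, log(0.3)))
  V <- stats::cov(coefs) / sigma2
  ev <- eigen(V, symmetric = TRUE)
  V <- ev$vectors %*% diag(pmax(ev$values, 1e-4), 2L) %*% t(ev$vectors)
  L <- t(chol(V))
  c(log(L[1L, 1L]), L[2L, 1L], log(max(L[2L, 2L], 1e-4)))
}

#' Fit the atrophy-rate mixed model by REML
#'
#' @param design An `lme_design` from [build_design()].
#' @param random `"slope"` (default; random intercept and slope, unstructured
#'   2x2 covariance) or `"intercept"` (random intercept only, for designs
#'   where no subject has repeated measurements).
#' @param maxit,reltol Optimizer control (Nelder-Mead on the log-Cholesky
#'   parameters of the relative covariance).
#' @return An `lme_fit`: fixed effects `beta` with covariance `cov_beta`,
#'   random-effects covariance `psi` (PSD), residual variance `sigma2`,
#'   REML criterion, per-group slope estimates with standard errors,
#'   convergence diagnostics, and a `boundary` flag for near-zero variance
#'   components. Subjects with a single measurement contribute through their
#'   marginal covariance.
#' @export
fit_lme <- function(design, random = c("slope", "intercept"),
                    maxit = 500L, reltol = 1e-10) {
  stopifnot(inherits(design, "lme_design"))
  random <- match.arg(random)
  p <- ncol(design$X)
  if (design$n_obs <= p)
    lm_error("longmorph_domain_error",
             "need more observations than fixed-effect parameters")
  n_repeat <- sum(tapply(design$time, design$subject,
                         function(tt) length(unique(tt))) >= 2L)
  if (random == "slope" && n_repeat < 2L)
    lm_error("longmorph_domain_error",
             paste("fewer than 2 subjects with repeated visits: the slope",
                   "variance is unidentifiable; refit with random =",
                   "'intercept'"))
  if (qr(design$X)$rank < p)
    lm_error("longmorph_domain_error",
             paste("fixed-effect design is rank deficient (e.g. no",
                   "follow-up visits, or a group absent): the 8-parameter",
                   "model is not estimable"))
  patterns <- build_patterns(design)
  # random-intercept mode uses a 1-column Z
  if (random == "intercept")
    patterns <- lapply(patterns, function(pat) { pat$t <- pat$t * 0; pat })
  objective <- function(theta) {
    G2 <- theta_to_G(theta)
    if (random == "intercept") {
      G <- matrix(0, 2L, 2L); G[1L, 1L] <- G2[1L, 1L]
    } else G <- G2
    v <- reml_eval(patterns, if (random == "intercept")
      matrix(c(G[1L, 1L], 0, 0, 0), 2L, 2L) else G, p, design$n_obs)
    if (is.null(v) || !is.finite(v)) return(1e10)
    v
  }
  start <- mom_start(design, random)
  opt <- if (length(start) == 1L)
    stats::optim(start, objective, method = "Brent", lower = -15, upper = 15,
                 control = list(maxit = maxit))
  else
    stats::optim(start, objective, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
  if (opt$convergence != 0 && opt$convergence != 10)
    lm_error("longmorph_convergence_error",
             "REML optimization did not converge (code %d, value %.6g)",
             opt$convergence, opt$value)
  theta <- opt$par
  G <- theta_to_G(theta)
  Gfull <- if (random == "intercept")
    matrix(c(G[1L, 1L], 0, 0, 0), 2L, 2L) else G
  final <- reml_eval(patterns, Gfull, p, design$n_obs, want_beta = TRUE)
  if (is.null(final))
    lm_error("longmorph_convergence_error", "degenerate fit at the optimum")
  beta <- stats::setNames(final$beta, colnames(design$X))
  dimnames(final$cov_beta) <- list(colnames(design$X), colnames(design$X))
  psi <- final$sigma2 * Gfull
  slopes <- c(CTRL = beta[["time"]],
              PDN = beta[["time"]] + beta[["time:PDN"]],
              PDCI = beta[["time"]] + beta[["time:PDCI"]])
  Cmat <- final$cov_beta
  se_of <- function(w) sqrt(drop(t(w) %*% Cmat %*% w))
  w_pdn <- as.numeric(.FIXED_NAMES %in% c("time", "time:PDN"))
  w_pdci <- as.numeric(.FIXED_NAMES %in% c("time", "time:PDCI"))
  w_ctrl <- as.numeric(.FIXED_NAMES == "time")
  slope_se <- c(CTRL = se_of(w_ctrl), PDN = se_of(w_pdn), PDCI = se_of(w_pdci))
  structure(list(beta = beta, cov_beta = Cmat, psi = psi,
                 sigma2 = final$sigma2,
                 reml_criterion = final$objective,
                 reml_logLik = -final$objective / 2,
                 theta = theta, random = random,
                 slopes = slopes, slope_se = slope_se,
                 n_obs = design$n_obs, n_subjects = design$n_subjects,
                 df_residual = design$n_obs - p,
                 boundary = any(diag(Gfull)[if (random == "intercept") 1L else
                   1:2] < 1e-6),
                 convergence = opt$convergence,
                 optim_value = opt$value,
                 design = design, patterns = patterns),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("REML mixed-effect fit: %d obs, %d subjects (region %s)\n",
              x$n_obs, x$n_subjects, x$design$region))
  print(round(rbind(estimate = x$beta, se = sqrt(diag(x$cov_beta))), 5))
  cat(sprintf("sigma = %.5g; random-effect SDs = %s; boundary = %s\n",
              sqrt(x$sigma2),
              paste(signif(sqrt(diag(x$psi)), 4), collapse = ", "),
              x$boundary))
  invisible(x)
}

#' Default slope-equality contrast
#'
#' Selects the two group-by-time interaction coefficients, so the null
#' hypothesis is that the atrophy rates of both patient groups equal the
#' control rate.
#'
#' @return A 2 x 8 contrast matrix.
#' @export
slope_contrast <- function() {
  L <- matrix(0, 2L, 8L, dimnames = list(NULL, .FIXED_NAMES))
  L[1L, "time:PDN"] <- 1
  L[2L, "time:PDCI"] <- 1
  L
}

# un-profiled -2 REML log-likelihood as a function of (theta, log sigma2),
# used for the Satterthwaite variance of variance parameters
reml_deviance_phi <- function(fit, phi) {
  ntheta <- length(fit$theta)
  G <- theta_to_G(phi[seq_len(ntheta)])
  Gfull <- if (fit$random == "intercept")
    matrix(c(G[1L, 1L], 0, 0, 0), 2L, 2L) else G
  sigma2 <- exp(phi[ntheta + 1L])
  p <- ncol(fit$design$X)
  v <- reml_eval(fit$patterns, Gfull, p, fit$n_obs, want_beta = TRUE)
  if (is.null(v)) return(NA_real_)
  n <- fit$n_obs
  # recompose at fixed sigma2 instead of the profiled one
  rss <- v$sigma2 * (n - p)
  (v$objective - (n - p) * (1 + log(2 * pi * v$sigma2))) +
    (n - p) * log(2 * pi * sigma2) + rss / sigma2
}

cov_beta_phi <- function(fit, phi) {
  ntheta <- length(fit$theta)
  G <- theta_to_G(phi[seq_len(ntheta)])
  Gfull <- if (fit$random == "intercept")
    matrix(c(G[1L, 1L], 0, 0, 0), 2L, 2L) else G
  sigma2 <- exp(phi[ntheta + 1L])
  p <- ncol(fit$design$X)
  v <- reml_eval(fit$patterns, Gfull, p, fit$n_obs, want_beta = TRUE)
  if (is.null(v)) return(NULL)
  v$cov_beta / v$sigma2 * sigma2
}

num_grad <- function(f, x, h = 1e-4) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

num_hessian <- function(f, x, h = 1e-3) {
  k <- length(x)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- numeric(k); ei[i] <- h
    ej <- numeric(k); ej[j] <- h
    if (i == j) {
      H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    } else {
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

satterthwaite_df <- function(fit, L) {
  phi <- c(fit$theta, log(fit$sigma2))
  A <- tryCatch({
    H <- num_hessian(function(p) reml_deviance_phi(fit, p), phi)
    2 * solve(H)
  }, error = function(e) NULL)
  if (is.null(A)) return(NA_real_)
  VL <- L %*% fit$cov_beta %*% t(L)
  eg <- eigen(VL, symmetric = TRUE)
  q <- nrow(L)
  nus <- vapply(seq_len(q), function(k) {
    v <- eg$vectors[, k]
    gfun <- function(p) {
      Cb <- cov_beta_phi(fit, p)
      if (is.null(Cb)) return(NA_real_)
      drop(t(v) %*% L %*% Cb %*% t(L) %*% v)
    }
    g <- gfun(phi)
    grad <- num_grad(gfun, phi)
    den <- drop(t(grad) %*% A %*% grad)
    if (den <= 0) return(Inf)
    2 * g^2 / den
  }, numeric(1))
  if (q == 1L) return(nus)
  nus_ok <- nus[nus > 2]
  if (length(nus_ok) < q) return(NA_real_)
  E <- sum(nus_ok / (nus_ok - 2))
  if (E <= q) return(Inf)
  2 * E / (E - q)
}

#' Contrast F-test on the fixed effects
#'
#' Computes `F = (L b)' (L C L')^{-1} (L b) / rank(L)` with `C` the estimated
#' covariance of the fixed effects, numerator degrees of freedom `rank(L)`,
#' and denominator degrees of freedom either the residual count
#' `n_obs - 8` (default) or a Satterthwaite approximation (numeric, with the
#' Fai-Cornelius combination for multi-row contrasts).
#'
#' @param fit An `lme_fit`.
#' @param L Contrast matrix with 8 columns and full row rank; defaults to
#'   [slope_contrast()] (slope equality across groups, DF1 = 2).
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @return A `contrast_test` with `F`, `DF1`, `DF2`, `p`, and the method tag.
#' @export
contrast_F_test <- function(fit, L = slope_contrast(),
                            df_method = c("residual", "satterthwaite")) {
  stopifnot(inherits(fit, "lme_fit"))
  df_method <- match.arg(df_method)
  L <- rbind(L)
  if (ncol(L) != length(fit$beta))
    lm_error("longmorph_contrast_error", "L must have %d columns",
             length(fit$beta))
  r <- qr(L)$rank
  if (r < nrow(L))
    lm_error("longmorph_contrast_error", "contrast matrix is rank deficient")
  Lb <- drop(L %*% fit$beta)
  M <- L %*% fit$cov_beta %*% t(L)
  Fstat <- drop(t(Lb) %*% solve(M, Lb)) / r
  DF2 <- if (df_method == "residual") fit$df_residual else
    satterthwaite_df(fit, L)
  if (!is.finite(DF2) || is.na(DF2)) {
    DF2 <- fit$df_residual
    df_method <- "residual (satterthwaite fallback)"
  }
  p <- stats::pf(Fstat, r, DF2, lower.tail = FALSE)
  structure(list(F = Fstat, DF1 = r, DF2 = DF2, p = p,
                 df_method = df_method, L = L),
            class = "contrast_test")
}

#' @export
print.contrast_test <- function(x, ...) {
  cat(sprintf("contrast F = %.4g, DF1 = %d, DF2 = %.4g, p = %.4g (%s)\n",
              x$F, x$DF1, x$DF2, x$p, x$df_method))
  invisible(x)
}

#' Render an atrophy rate in display units
#'
#' Thickness rates are conventionally reported in micrometers per year,
#' volumes in cm^3 per year, planar areas in mm^2 per year.
#'
#' @param rate Numeric rate in native units per year (mm/y for thickness).
#' @param kind Region kind (`"volume"`, `"area"`, `"thickness"`).
#' @return Character rendering, e.g. `-0.028` mm/y as `"-28 um/y"`.
#' @export
format_rate <- function(rate, kind) {
  if (kind == "thickness") sprintf("%.3g um/y", rate * 1000)
  else if (kind == "area") sprintf("%.3g mm^2/y", rate)
  else sprintf("%.3g cm^3/y", rate)
}

#' Per-region atrophy-rate report
#'
#' @param fits Named list (region -> `lme_fit`).
#' @param region_kinds Optional named character vector region -> kind, used
#'   for display units.
#' @param df_method Passed to [contrast_F_test()].
#' @param alpha Familywise significance level for the Bonferroni flag.
#' @return A `data.frame` with one row per region: per-group rates (controls,
#'   PD-N, PD-CI), contrast F/DF1/DF2/p, Bonferroni-adjusted p and flag.
#' @export
slope_table <- function(fits, region_kinds = NULL,
                        df_method = c("residual", "satterthwaite"),
                        alpha = 0.05) {
  df_method <- match.arg(df_method)
  rows <- lapply(names(fits), function(r) {
    fit <- fits[[r]]
    ct <- contrast_F_test(fit, df_method = df_method)
    kind <- if (!is.null(region_kinds)) region_kinds[[r]] else NA_character_
    data.frame(region = r, kind = kind,
               rate_ctrl = fit$slopes[["CTRL"]],
               rate_pdn = fit$slopes[["PDN"]],
               rate_pdci = fit$slopes[["PDCI"]],
               rate_ctrl_display = if (is.na(kind)) NA_character_ else
                 format_rate(fit$slopes[["CTRL"]], kind),
               rate_pdn_display = if (is.na(kind)) NA_character_ else
                 format_rate(fit$slopes[["PDN"]], kind),
               rate_pdci_display = if (is.na(kind)) NA_character_ else
                 format_rate(fit$slopes[["PDCI"]], kind),
               F = ct$F, DF1 = ct$DF1, DF2 = ct$DF2, p = ct$p,
               boundary = fit$boundary,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  out$significant <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}
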