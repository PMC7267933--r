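# Robust locally weighted scatterplot smoothing (Cleveland-style LOWESS).
#
# At each evaluation point the q = ceiling(f * n) nearest neighbours are
# selected, weighted with the tricube kernel W(u) = (1 - |u|^3)^3 on
# u = |x - x0| / (largest neighbour distance), and a weighted polynomial of
# degree d is fitted; the smoothed value is the fit at x0. Robustness
# iterations then down-weight gross outliers with the bisquare weight
# B(e) = (1 - (e / 6m)^2)^2 for |e| < 6m, m = median absolute residual.

#' LOWESS configuration
#'
#' Defaults follow the exploratory-trajectory settings used throughout the
#' package: 80% of the data in each sliding window, local straight-line fits,
#' two robustness iterations.
#'
#' @param f Fraction of data points within the sliding window, in (0, 1].
#' @param degree Local polynomial degree, 0, 1 or 2.
#' @param robust_iters Number of bisquare robustness iterations (>= 0).
#' @param eval_points Optional grid of abscissae at which to read the smooth
#'   out; default is the observed x values.
#' @return A `lowess_config` list.
#' @export
lowess_config <- function(f = 0.8, degree = 1L, robust_iters = 2L,
                          eval_points = NULL) {
  if (!(f > 0 && f <= 1))
    lm_error("longmorph_config_error", "f must lie in (0, 1]")
  if (!degree %in% 0:2)
    lm_error("longmorph_config_error", "degree must be 0, 1 or 2")
  if (robust_iters < 0)
    lm_error("longmorph_config_error", "robust_iters must be >= 0")
  structure(list(f = f, degree = as.integer(degree),
                 robust_iters = as.integer(robust_iters),
                 eval_points = eval_points),
            class = "lowess_config")
}

# one pass of local weighted polynomial fits at x0s, given per-point
# robustness weights rw (aligned with x)
lowess_pass <- function(x, y, x0s, q, degree, rw) {
  n <- length(x)
  vapply(x0s, function(x0) {
    dist <- abs(x - x0)
    h <- sort(dist, partial = q)[q]
    if (h == 0) {
      # replicated x at the window edge: uniform weights over the replicates
      w <- as.numeric(dist == 0)
    } else {
      u <- dist / h
      w <- ifelse(u < 1, (1 - u^3)^3, 0)
    }
    w <- w * rw
    use <- w > 0
    if (!any(use)) {
      # all neighbours robust-rejected: fall back to tricube only
      w <- ifelse(dist / max(h, .Machine$double.eps) < 1,
                  (1 - (dist / max(h, .Machine$double.eps))^3)^3, 0)
      use <- w > 0
    }
    deg <- degree
    # reduce the degree to what the window can estimate
    while (deg > 0 && length(unique(x[use])) < deg + 1L) deg <- deg - 1L
    xc <- x[use] - x0
    X <- stats::poly(xc, degree = max(deg, 1L), raw = TRUE, simple = TRUE)
    X <- cbind(1, X[, seq_len(deg), drop = FALSE])
    fit <- stats::lm.wfit(X, y[use], w[use])
    fit$coefficients[1L]
  }, numeric(1))
}

#' Fit a robust LOWESS curve
#'
#' @param x,y Paired observations; `x` must be finite with at least
#'   `max(3, degree + 2)` points and not all identical.
#' @param config A [lowess_config()].
#' @return A `lowess_curve`: sorted abscissae `x`, smoothed `fitted` values,
#'   final per-point `robustness_weights` in \[0, 1\] (aligned with `x`), and
#'   the data and configuration needed to read the smooth out at new points.
#' @examples
#' set.seed(1)
#' x <- sort(runif(60, 0, 4)); y <- 1200 - 5 * x + rnorm(60, 0, 4)
#' curve <- lowess_fit(x, y, lowess_config())
#' annual_rate_readout(curve, x0 = 2, window = 1)
#' @export
lowess_fit <- function(x, y, config = lowess_config()) {
  stopifnot(inherits(config, "lowess_config"))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < max(3L, config$degree + 2L))
    lm_error("longmorph_domain_error",
             "need at least max(3, degree + 2) finite points")
  if (length(unique(x)) == 1L)
    lm_error("longmorph_domain_error", "all x values identical")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  q <- min(n, as.integer(ceiling(config$f * n)))
  rw <- rep.int(1, n)
  fitted_at_data <- lowess_pass(x, y, x, q, config$degree, rw)
  iters <- config$robust_iters
  for (it in seq_len(iters)) {
    r <- y - fitted_at_data
    m <- stats::median(abs(r))
    if (m == 0) break
    u <- r / (6 * m)
    rw <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    fitted_at_data <- lowess_pass(x, y, x, q, config$degree, rw)
  }
  xe <- if (is.null(config$eval_points)) x else sort(config$eval_points)
  fitted <- if (is.null(config$eval_points)) fitted_at_data else
    lowess_pass(x, y, xe, q, config$degree, rw)
  structure(list(x = xe, fitted = fitted, robustness_weights = rw,
                 data = list(x = x, y = y), q = q, config = config),
            class = "lowess_curve")
}

#' Evaluate a fitted LOWESS curve at new abscissae
#'
#' Re-runs the local fits at `x0` using the curve's data and final robustness
#' weights (no further robustness iterations).
#'
#' @param curve A `lowess_curve`.
#' @param x0 Abscissae at which to evaluate.
#' @return Smoothed values at `x0`.
#' @export
lowess_predict <- function(curve, x0) {
  stopifnot(inherits(curve, "lowess_curve"))
  lowess_pass(curve$data$x, curve$data$y, x0, curve$q,
              curve$config$degree, curve$robustness_weights)
}

#' Annual rate of change read out from a smoothed trajectory
#'
#' Central-difference slope of the smoothed curve at `x0`, in outcome units
#' per year, together with the rate as a percentage of the smoothed level at
#' `x0` (negative = loss).
#'
#' @param curve A `lowess_curve` over time in years.
#' @param x0 Time (years) at which to read the rate.
#' @param window Width (years) of the central difference; `x0 +/- window/2`
#'   must lie inside the curve's support.
#' @return List with `rate` (units/year), `percent_per_year`, and `level`
#'   (smoothed value at `x0`).
#' @export
annual_rate_readout <- function(curve, x0, window) {
  stopifnot(inherits(curve, "lowess_curve"), window > 0)
  rng <- range(curve$data$x)
  if (x0 - window / 2 < rng[1L] || x0 + window / 2 > rng[2L])
    lm_error("longmorph_domain_error",
             "x0 +/- window/2 outside the curve support [%g, %g]",
             rng[1L], rng[2L])
  fx <- lowess_predict(curve, c(x0 - window / 2, x0, x0 + window / 2))
  rate <- (fx[3L] - fx[1L]) / window
  list(rate = rate, percent_per_year = rate / fx[2L] * 100, level = fx[2L])
}
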