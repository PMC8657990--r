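#' Initial rate of fluorescein formation from an absorbance trace
#'
#' Estimates the early-time rate of probe oxidation from a 490 nm kinetic
#' trace and converts it to a fluorescein production rate through the
#' Beer-Lambert optics. Two estimators are provided:
#'
#' * `"tangent"` (default): a cubic progress-curve polynomial is fitted on
#'   the window and its derivative at the window start is reported. Over a
#'   600 s window the donor pool decays appreciably (first-order, half-life
#'   ~14 min), so the progress curve is measurably concave; the tangent
#'   estimator recovers the true initial rate to ~0.1% on the
#'   quasi-steady-state curve, where a straight-line slope would be ~20%
#'   low.
#' * `"linear"`: the plain ordinary-least-squares slope over the window,
#'   the textbook estimator for genuinely linear stretches.
#'
#' @param trace A `kinetic_trace` (or data frame with `time_s`,
#'   `absorbance_490`).
#' @param optics The [optics_model()] used to convert absorbance slope to
#'   concentration rate.
#' @param window Two-element numeric, fitting window in s. Default: first
#'   600 s of the trace (or the whole trace if shorter).
#' @param method `"tangent"` or `"linear"`.
#' @param mixing_lag If `TRUE`, the first 30 s are dropped from the window
#'   to discard a mixing artefact; off by default.
#' @return An object of class `initial_rate`: list with `rate` and `se`
#'   (M/s), `slope_AU` and `slope_se_AU` (AU/s), `method`, `window`,
#'   `n_points`, and `nonpositive` flag (a non-positive fitted rate is
#'   returned as-is, flagged).
#' @examples
#' tr <- simulate_trace(rate_constants(), experiment_conditions(),
#'                      optics_model(noise_sd = 0))
#' initial_rate(tr, optics_model(noise_sd = 0))
#' @export
initial_rate <- function(trace, optics = optics_model(), window = NULL,
                         method = c("tangent", "linear"),
                         mixing_lag = FALSE) {
  method <- match.arg(method)
  optics <- as_optics_model(optics)
  t <- trace$time_s
  a <- trace$absorbance_490
  if (is.null(window)) window <- c(0, min(600, max(t)))
  if (mixing_lag) window[1] <- max(window[1], 30)
  keep <- t >= window[1] & t <= window[2]
  if (sum(keep) < 5)
    stop("fewer than 5 samples inside the fitting window [",
         window[1], ", ", window[2], "] s")
  t <- t[keep]; a <- a[keep]
  span <- diff(range(t))
  s <- (t - t[1]) / span
  if (method == "tangent") {
    fit <- stats::lm(a ~ s + I(s^2) + I(s^3))
  } else {
    fit <- stats::lm(a ~ s)
  }
  slope_scaled <- stats::coef(fit)[["s"]]
  se_scaled <- lm_coef_se(fit)[["s"]]
  slope <- slope_scaled / span
  slope_se <- se_scaled / span
  eps_eff <- (optics$epsilon_FlOH_490 - optics$epsilon_FlBA_490) *
    optics$path_length
  if (eps_eff <= 0)
    stop("effective absorptivity (epsilon_FlOH - epsilon_FlBA) * l must be > 0")
  structure(list(rate = slope / eps_eff, se = slope_se / eps_eff,
                 slope_AU = slope, slope_se_AU = slope_se,
                 method = method, window = window,
                 n_points = length(t), nonpositive = slope <= 0),
            class = "initial_rate")
}

#' @export
print.initial_rate <- function(x, ...) {
  cat(sprintf(
    "Initial rate (%s fit, %d points on [%g, %g] s): %.4g +/- %.2g M/s%s\n",
    x$method, x$n_points, x$window[1], x$window[2], x$rate, x$se,
    if (x$nonpositive) "  [non-positive]" else ""))
  invisible(x)
}

#' Donor decomposition rate constant from a control trace rate
#'
#' In the absence of scavenger every HNO equivalent is routed to
#' fluorescein, so the control rate equals `k_AS * [AS]0` and the
#' first-order donor constant follows by division.
#'
#' @param control_rate Fluorescein formation rate of a control run, M/s
#'   (numeric, or an [initial_rate()] object).
#' @param AS0 Initial donor concentration, M (> 0).
#' @return Estimated `k_AS` in 1/s, with the propagated standard error as
#'   attribute `"se"` when available.
#' @examples
#' estimate_k_as(1.6e-8, uM(20))  # 8e-4 1/s
#' @export
estimate_k_as <- function(control_rate, AS0) {
  if (AS0 <= 0) stop("'AS0' must be > 0")
  se <- NA_real_
  if (inherits(control_rate, "initial_rate")) {
    se <- control_rate$se
    control_rate <- control_rate$rate
  }
  structure(control_rate / AS0, se = se / AS0)
}

#' HNO flux delivered by the donor
#'
#' @param k_AS First-order donor decomposition rate constant, 1/s.
#' @param AS0 Initial donor concentration, M.
#' @return Initial HNO release rate `k_AS * AS0`, M/s.
#' @examples
#' hno_flux(8.0e-4, uM(20)) * 1e6  # 0.016 uM/s
#' @export
hno_flux <- function(k_AS, AS0) {
  if (k_AS < 0 || AS0 < 0) stop("'k_AS' and 'AS0' must be >= 0")
  as.numeric(k_AS) * AS0
}

#' Donor concentration from its 248 nm absorbance
#'
#' Beer-Lambert quantitation of an Angeli's salt stock using the donor's
#' 248 nm band (molar absorptivity 8.3e3 1/(M cm)).
#'
#' @param A248 Absorbance at 248 nm, AU (>= 0).
#' @param path_length Optical path length, cm.
#' @return Donor concentration, M.
#' @examples
#' as_concentration_from_absorbance(0.83)  # 1e-4 M
#' @export
as_concentration_from_absorbance <- function(A248, path_length = 1) {
  if (any(A248 < 0)) stop("'A248' must be >= 0")
  if (path_length <= 0) stop("'path_length' must be > 0")
  A248 / (8.3e3 * path_length)
}

#' Inhibition points of a competition series
#'
#' Reduces a competition series to the points of the competition plot: for
#' every inhibited trace, `y = v0/vi - 1` against
#' `x = [nucleophile]/[O2]`, with `v0` from the series control and `vi`
#' from that trace, both via [initial_rate()]. Traces whose fitted rate is
#' non-positive (noise-dominated runs) are excluded with a warning.
#'
#' @param series A `competition_series` from [generate_series()] or
#'   [read_series()].
#' @param optics Readout model; defaults to the one stored in the series.
#' @param window,method Passed to [initial_rate()].
#' @return An `inhibition_points` data frame with columns `conc_M`,
#'   `replicate`, `x`, `y`, `vi`, `vi_se`, and attributes `v0`, `v0_se`,
#'   `o2`, `k_O2`.
#' @export
inhibition_points <- function(series, optics = NULL, window = NULL,
                              method = "tangent") {
  if (is.null(optics)) optics <- series$optics
  optics <- as_optics_model(optics)
  ctrl <- initial_rate(series$control, optics, window, method)
  if (ctrl$nonpositive)
    stop("control trace has a non-positive fitted rate; v0 undefined")
  o2 <- series$conditions$O2
  rows <- lapply(series$inhibited, function(tr) {
    md <- attr(tr, "metadata")
    ir <- initial_rate(tr, optics, window, method)
    data.frame(conc_M = md$nucleophile_conc, replicate = md$replicate,
               x = md$nucleophile_conc / o2,
               y = ctrl$rate / ir$rate - 1,
               vi = ir$rate, vi_se = ir$se)
  })
  pts <- do.call(rbind, rows)
  bad <- pts$vi <= 0
  if (any(bad)) {
    warning(sum(bad), " trace(s) with non-positive fitted rate excluded ",
            "from the competition plot")
    pts <- pts[!bad, , drop = FALSE]
  }
  structure(pts, class = c("inhibition_points", "data.frame"),
            v0 = ctrl$rate, v0_se = ctrl$se, o2 = o2,
            k_O2 = series$rates_true$k_O2)
}

#' Competition-slope estimate of the scavenger rate constant
#'
#' Fits the competition line `y = slope * x` through the origin (the
#' competition law has no intercept) and converts the slope to the
#' second-order scavenger rate constant `k_hat = slope * k_O2`.
#'
#' When per-trace rate uncertainties are available (noisy traces), the fit
#' is generalized least squares with the full measurement covariance of
#' the points: each `y = v0/vi - 1` carries its own `vi` variance, and all
#' points share the variance of the common control `v0` (a rank-one
#' covariance term). With exact (noiseless) points the fit reduces to
#' ordinary least squares through the origin with a residual-based
#' standard error. A free-intercept ordinary fit is run alongside as a
#' diagnostic; a warning is raised if its intercept exceeds twice its
#' standard error, which flags lack of fit to the competition law.
#'
#' @param points An `inhibition_points` data frame (or any data frame with
#'   `x`, `y` and optionally `vi`, `vi_se`, `replicate` columns plus `v0`,
#'   `v0_se` attributes).
#' @param k_O2 Reference rate constant of the HNO + O2 channel, 1/(M s);
#'   defaults to the value carried by `points`, else 1.8e4.
#' @param conf_level Confidence level of the reported interval.
#' @return An object of class `rate_estimate` with fields
#'   `k_nucleophile_hat`, `k_se`, `ci`, `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `n_points`, `per_replicate_estimates`, `k_O2`,
#'   `fit_method`.
#' @examples
#' pts <- data.frame(x = c(1, 2, 4), y = c(0.5, 1, 2))
#' competition_fit(pts, k_O2 = 1.8e4)  # exact line: slope 0.5, k = 9000
#' @export
competition_fit <- function(points, k_O2 = NULL, conf_level = 0.95) {
  if (is.null(k_O2)) k_O2 <- attr(points, "k_O2")
  if (is.null(k_O2)) k_O2 <- 1.8e4
  x <- points$x; y <- points$y
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2)
    stop("need at least 2 points spanning at least 2 distinct ",
         "[nucleophile]/[O2] values")

  v0 <- attr(points, "v0"); v0_se <- attr(points, "v0_se")
  have_meas_err <- !is.null(v0) && !is.null(v0_se) && is.finite(v0_se) &&
    v0_se > 0 && !is.null(points$vi_se) && all(is.finite(points$vi_se)) &&
    all(points$vi_se > 0)

  if (have_meas_err) {
    # GLS through the origin: Sigma = diag(d) + a^2 r r', r_j = v0 / vi_j.
    # r and the per-point variances are evaluated on the fitted line (one
    # reweighting pass from a pilot OLS slope), not on the measured vi:
    # weights computed from the noisy vi themselves correlate with the
    # errors and bias the slope downward.
    slope0 <- sum(x * y) / sum(x^2)
    r <- 1 + pmax(slope0 * x, 0)
    a2 <- (v0_se / v0)^2
    d <- r^2 * (points$vi_se * r / v0)^2
    Sigma <- diag(d, n) + a2 * tcrossprod(r)
    W <- solve(Sigma)
    xtWx <- drop(crossprod(x, W %*% x))
    slope <- drop(crossprod(x, W %*% y)) / xtWx
    slope_se <- sqrt(1 / xtWx)
    fit_method <- "gls"
  } else {
    slope <- sum(x * y) / sum(x^2)
    resid <- y - slope * x
    slope_se <- if (n > 1) sqrt(sum(resid^2) / ((n - 1) * sum(x^2))) else NA_real_
    fit_method <- "ols"
  }

  free <- stats::lm(y ~ x)
  intercept <- stats::coef(free)[[1]]
  intercept_se <- lm_coef_se(free)[[1]]
  # warn on a statistically and practically non-zero intercept (the second
  # guard keeps near-exact data from tripping the test on a negligible
  # systematic, where the standard error is essentially zero)
  if (is.finite(intercept_se) && intercept_se > 0 &&
      abs(intercept) > 2 * intercept_se &&
      abs(intercept) > 0.01 * max(abs(y)))
    warning(sprintf(
      "free-intercept diagnostic fit has intercept %.3g (se %.2g), more than ",
      intercept, intercept_se),
      "2 se from zero: the competition law may not describe these points")

  per_rep <- NULL
  if (!is.null(points$replicate)) {
    per_rep <- vapply(split(seq_len(n), points$replicate), function(i) {
      if (length(i) < 1) return(NA_real_)
      sum(x[i] * y[i]) / sum(x[i]^2) * k_O2
    }, numeric(1))
  }

  k_hat <- slope * k_O2
  k_se <- slope_se * k_O2
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  structure(list(k_nucleophile_hat = k_hat, k_se = k_se,
                 ci = c(lower = k_hat - tq * k_se, upper = k_hat + tq * k_se),
                 conf_level = conf_level,
                 slope = slope, slope_se = slope_se,
                 intercept = intercept, intercept_se = intercept_se,
                 n_points = n, per_replicate_estimates = per_rep,
                 k_O2 = k_O2, fit_method = fit_method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Competition-slope rate estimate:\n")
  cat(sprintf("  k_nucleophile = %.4g +/- %.2g 1/(M s)   [%g%% CI %.4g, %.4g]\n",
              x$k_nucleophile_hat, x$k_se, 100 * x$conf_level,
              x$ci[["lower"]], x$ci[["upper"]]))
  cat(sprintf("  slope = %.4g (se %.2g, %s fit, %d points, k_O2 = %.3g)\n",
              x$slope, x$slope_se, x$fit_method, x$n_points, x$k_O2))
  if (!is.null(x$per_replicate_estimates))
    cat("  per-replicate k:",
        paste(signif(x$per_replicate_estimates, 4), collapse = ", "), "\n")
  invisible(x)
}

#' One-call rate-constant recovery from a competition series
#'
#' Convenience wrapper chaining [inhibition_points()] and
#' [competition_fit()].
#'
#' @inheritParams inhibition_points
#' @param ... Passed to [competition_fit()].
#' @return A `rate_estimate`.
#' @examples
#' ser <- generate_series(2.2e3, replicates = 1, seed = 7,
#'                        optics = optics_model(noise_sd = 0))
#' estimate_k_nucleophile(ser)
#' @export
estimate_k_nucleophile <- function(series, optics = NULL, window = NULL,
                                   method = "tangent", ...) {
  competition_fit(inhibition_points(series, optics, window, method), ...)
}
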