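#' Linear free-energy fit of activation barriers against log rate constants
#'
#' Ordinary least squares of the computed activation barrier (kJ/mol) on
#' the logarithm of the measured second-order rate constant, the classic
#' linear free-energy presentation of a structure-activity series: faster
#' scavengers have lower computed barriers, so the slope is negative.
#' Records missing either quantity are excluded and reported in the result.
#'
#' @param records Data frame with columns `k_M_per_s` and `barrier_kJ_mol`
#'   (and optionally `compound_id`, used to key the residuals), e.g.
#'   [hno_compounds()].
#' @param log_base Base of the logarithm applied to `k` (default 10).
#' @return An object of class `barrier_fit`: `slope` (kJ/mol per log-k
#'   unit), `intercept` (kJ/mol), `r_squared`, `n`, `residuals` (named by
#'   compound id), `excluded` (ids lacking a value), `log_base`.
#' @examples
#' fit_barrier_loglinear(hno_compounds())
#' @export
fit_barrier_loglinear <- function(records, log_base = 10) {
  if (!all(c("k_M_per_s", "barrier_kJ_mol") %in% names(records)))
    stop("'records' must have columns 'k_M_per_s' and 'barrier_kJ_mol'")
  ids <- if ("compound_id" %in% names(records)) records$compound_id
  else seq_len(nrow(records))
  ok <- is.finite(records$k_M_per_s) & records$k_M_per_s > 0 &
    is.finite(records$barrier_kJ_mol)
  if (sum(ok) < 3)
    stop("need at least 3 records with both a rate constant and a barrier ",
         "(got ", sum(ok), ")")
  logk <- log(records$k_M_per_s[ok], base = log_base)
  barrier <- records$barrier_kJ_mol[ok]
  fit <- stats::lm(barrier ~ logk)
  res <- stats::setNames(stats::residuals(fit), ids[ok])
  structure(list(slope = stats::coef(fit)[["logk"]],
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 r_squared = lm_r_squared(fit),
                 n = sum(ok),
                 residuals = res,
                 excluded = ids[!ok],
                 log_base = log_base),
            class = "barrier_fit")
}

#' @export
print.barrier_fit <- function(x, ...) {
  cat(sprintf(
    "Barrier vs log%g(k) fit (n = %d): slope = %.3f kJ/mol per log unit,\n",
    x$log_base, x$n, x$slope))
  cat(sprintf("  intercept = %.2f kJ/mol, R^2 = %.3f\n", x$intercept,
              x$r_squared))
  if (length(x$excluded))
    cat("  excluded (incomplete records):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Predict a rate constant from a computed barrier
#'
#' Inverts the linear free-energy line: `k = base^((barrier - intercept) /
#' slope)`. With the negative slope of the fitted series, the predicted
#' rate constant decreases monotonically with increasing barrier.
#'
#' @param fit A `barrier_fit` from [fit_barrier_loglinear()].
#' @param barrier Activation barrier(s), kJ/mol.
#' @return Predicted second-order rate constant(s), 1/(M s).
#' @examples
#' fit <- fit_barrier_loglinear(hno_compounds())
#' predict_rate_from_barrier(fit, 60)
#' @export
predict_rate_from_barrier <- function(fit, barrier) {
  if (!inherits(fit, "barrier_fit")) stop("'fit' must be a barrier_fit")
  if (!is.finite(fit$slope) || abs(fit$slope) < 1e-10)
    stop("zero slope: the line cannot be inverted")
  fit$log_base^((barrier - fit$intercept) / fit$slope)
}
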