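#' Quasi-steady-state HNO concentration
#'
#' Setting d\[HNO\]/dt = 0 in the network balances HNO release against its
#' first-order loss channels and gives
#' \deqn{[HNO]_{ss} = \frac{k_{AS}[AS]}{k_{nuc}[nuc] + k_{O2}[O_2]}.}
#' Dimerization, a second-order loss, is excluded from the closed form
#' (it is a sub-percent channel at the nM steady-state HNO levels of the
#' assay; see [flux_partition()] for the quantitative check against the
#' full model).
#'
#' @param rates A [rate_constants()] object.
#' @param conditions An [experiment_conditions()] object.
#' @return Steady-state HNO concentration, M.
#' @examples
#' hno_steady_state(rate_constants(), experiment_conditions())  # ~4 nM
#' @export
hno_steady_state <- function(rates, conditions) {
  rates <- as_rate_constants(rates)
  conditions <- as_experiment_conditions(conditions)
  denom <- rates$k_nucleophile * conditions$nucleophile0 +
    rates$k_O2 * conditions$O2
  if (denom <= 0)
    stop("no HNO loss channel: k_nucleophile*[nucleophile] + k_O2*[O2] ",
         "must be > 0 for a steady state to exist")
  conditions$hno_yield * rates$k_AS * conditions$AS0 / denom
}

#' Steady-state fluorescein formation rates
#'
#' Closed-form initial rates of fluorescein formation from the
#' quasi-steady-state treatment of the competition network:
#' `v0 = k_AS [AS]` in the absence of scavenger, and in its presence
#' \deqn{v_i = k_{AS}[AS] \cdot \frac{k_{O2}[O_2]}{k_{nuc}[nuc] + k_{O2}[O_2]},}
#' together with the steady-state HNO and peroxynitrite pools.
#'
#' @inheritParams hno_steady_state
#' @return An object of class `steady_state_rates` with fields `hno_ss`,
#'   `onoo_ss` (M; `onoo_ss` is `NA` with a warning when no probe is
#'   present), `v0` and `vi` (M/s).
#' @examples
#' fluorescein_rates(rate_constants(k_nucleophile = 2.2e3),
#'                   experiment_conditions(nucleophile0 = uM(1000)))
#' @export
fluorescein_rates <- function(rates, conditions) {
  rates <- as_rate_constants(rates)
  conditions <- as_experiment_conditions(conditions)
  hno <- hno_steady_state(rates, conditions)
  v0 <- conditions$hno_yield * rates$k_AS * conditions$AS0
  k_loss_nuc <- rates$k_nucleophile * conditions$nucleophile0
  k_loss_o2 <- rates$k_O2 * conditions$O2
  vi <- v0 * k_loss_o2 / (k_loss_nuc + k_loss_o2)
  if (conditions$FlBA0 > 0 && rates$k_FlBA > 0) {
    onoo <- k_loss_o2 * hno / (rates$k_FlBA * conditions$FlBA0)
  } else {
    warning("no probe present (FlBA0 or k_FlBA is zero): ",
            "steady-state [ONOO-] is undefined")
    onoo <- NA_real_
  }
  structure(list(hno_ss = hno, onoo_ss = onoo, v0 = v0, vi = vi),
            class = "steady_state_rates")
}

#' @export
print.steady_state_rates <- function(x, ...) {
  cat("Quasi-steady-state solution:\n")
  cat(sprintf("  [HNO]ss  = %.4g M   [ONOO-]ss = %.4g M\n", x$hno_ss, x$onoo_ss))
  cat(sprintf("  v0 = %.4g M/s   vi = %.4g M/s   (vi/v0 = %.4f)\n",
              x$v0, x$vi, x$vi / x$v0))
  invisible(x)
}

#' Predicted inhibition statistic
#'
#' The competition law relates the fractional slowdown of probe oxidation
#' to the scavenger and oxygen pools:
#' \deqn{\frac{v_0}{v_i} - 1 = \frac{k_{nuc}}{k_{O2}} \cdot \frac{[nuc]}{[O_2]}.}
#' This is the model line on which the slope estimator operates; it is an
#' algebraic identity with the ratio `v0/vi - 1` from
#' [fluorescein_rates()].
#'
#' @param rates A [rate_constants()] object.
#' @param nucleophile_conc Scavenger concentration, M.
#' @param o2_conc Dissolved oxygen concentration, M (must be > 0).
#' @return Dimensionless predicted value of `v0/vi - 1`.
#' @examples
#' inhibition_prediction(rate_constants(k_nucleophile = 2.2e3), uM(1000), uM(225))
#' @export
inhibition_prediction <- function(rates, nucleophile_conc, o2_conc) {
  rates <- as_rate_constants(rates)
  if (o2_conc <= 0) stop("'o2_conc' must be > 0")
  if (nucleophile_conc < 0) stop("'nucleophile_conc' must be >= 0")
  (rates$k_nucleophile / rates$k_O2) * (nucleophile_conc / o2_conc)
}
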