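# Species tracked by the full reaction-network model, all in M:
#   AS          Angeli's salt (HNO donor)
#   HNO         azanone
#   ONOO        peroxynitrite (HNO + O2 product)
#   FlBA        intact boronate probe
#   FlOH        fluorescein (probe oxidation product, the 490 nm readout)
#   nucleophile C-nucleophile scavenger
#   adduct      HNO-nucleophile addition product
#   N2O         nitrous oxide (2 HNO -> N2O + H2O)
#   NO2         nitrite from probe turnover (ONOO- + FlBA -> FlOH + NO2-)
#   O2          dissolved oxygen (held constant when o2_clamped)
species_names <- c("AS", "HNO", "ONOO", "FlBA", "FlOH",
                   "nucleophile", "adduct", "N2O", "NO2", "O2")

#' Right-hand side of the full reaction-network model
#'
#' Time derivatives of all species in the donor/probe competition network:
#' first-order HNO release from Angeli's salt, HNO consumption by O2 (giving
#' peroxynitrite), by the scavenger (giving the C-adduct) and by
#' dimerization (`d[HNO]/dt` loses `2 k_dim [HNO]^2`, `d[N2O]/dt` gains
#' `k_dim [HNO]^2`), and stoichiometric probe turnover
#' (ONOO- + FlBA -> FlOH + NO2-). When `conditions$o2_clamped` is `TRUE`
#' the O2 derivative is zero and the clamped value is taken from the state.
#'
#' @param state Named numeric vector of species concentrations in M; see
#'   [new_state()] for construction. All entries must be non-negative.
#' @param rates A [rate_constants()] object.
#' @param conditions An [experiment_conditions()] object.
#' @return Named numeric vector of time derivatives, M/s.
#' @examples
#' st <- new_state(experiment_conditions())
#' rhs_full_model(st, rate_constants(), experiment_conditions())
#' @export
rhs_full_model <- function(state, rates, conditions) {
  if (!all(species_names %in% names(state)))
    stop("state must contain all species: ",
         paste(setdiff(species_names, names(state)), collapse = ", "))
  if (any(state[species_names] < 0))
    stop("negative concentration in state: ",
         paste(species_names[state[species_names] < 0], collapse = ", "))
  d <- rhs_raw(state[species_names], rates, conditions)
  names(d) <- species_names
  d
}

# unchecked numeric core shared with the integrator (state in species order)
rhs_raw <- function(y, rates, conditions) {
  o2 <- y[[10L]]
  r_as  <- rates$k_AS * y[[1L]]
  r_o2  <- rates$k_O2 * o2 * y[[2L]]
  r_nuc <- rates$k_nucleophile * y[[6L]] * y[[2L]]
  r_dim <- rates$k_dim * y[[2L]]^2
  r_pr  <- rates$k_FlBA * y[[4L]] * y[[3L]]
  r_dec <- rates$k_onoo_decay * y[[3L]]
  c(-r_as,
    conditions$hno_yield * r_as - r_o2 - r_nuc - 2 * r_dim,
    r_o2 - r_pr - r_dec,
    -r_pr,
    r_pr,
    -r_nuc,
    r_nuc,
    r_dim,
    r_pr,
    if (conditions$o2_clamped) 0 else -r_o2)
}

#' Initial state vector for the network model
#'
#' @param conditions An [experiment_conditions()] object.
#' @return Named numeric vector over all model species (M), with the donor,
#'   probe, scavenger and O2 pools at their initial concentrations and all
#'   products at zero.
#' @export
new_state <- function(conditions) {
  conditions <- as_experiment_conditions(conditions)
  stats::setNames(
    c(conditions$AS0, 0, 0, conditions$FlBA0, 0,
      conditions$nucleophile0, 0, 0, 0, conditions$O2),
    species_names)
}

#' Integrate the full reaction network
#'
#' Solves the stiff initial-value problem for the complete donor/probe
#' network with `deSolve::lsoda`. The rate constants span ten orders of
#' magnitude (1e-4 to 1e6), so a stiff-capable integrator and a tight
#' absolute tolerance are required: the steady-state HNO pool sits at a few
#' nM and must be resolved accurately (defaults `rtol = 1e-8`,
#' `atol = 1e-14` M). Tiny negative excursions produced by the integrator
#' (below atol) are clipped to zero.
#'
#' @param rates A [rate_constants()] object.
#' @param conditions An [experiment_conditions()] object.
#' @param time_grid Strictly increasing numeric vector of output times in s,
#'   starting at 0. Defaults to a 1 s grid over `conditions$duration`.
#' @param rtol,atol Integration tolerances passed to `deSolve::lsoda`.
#' @return A `hno_trajectory`: a data frame with column `time_s` and one
#'   column per species (M), carrying the rates and conditions as
#'   attributes.
#' @examples
#' tr <- integrate_full_model(rate_constants(), experiment_conditions())
#' tail(tr[, c("time_s", "AS", "FlOH")])
#' @export
integrate_full_model <- function(rates, conditions, time_grid = NULL,
                                 rtol = 1e-8, atol = 1e-14) {
  rates <- as_rate_constants(rates)
  conditions <- as_experiment_conditions(conditions)
  if (is.null(time_grid))
    time_grid <- seq(0, conditions$duration, by = min(1, conditions$duration / 50))
  if (length(time_grid) < 2L || time_grid[1L] != 0 ||
      any(diff(time_grid) <= 0))
    stop("time_grid must be strictly increasing and start at 0")
  y0 <- new_state(conditions)
  f <- function(t, y, p) list(rhs_raw(pmax(y, 0), rates, conditions))
  sol <- deSolve::lsoda(y0, time_grid, f, parms = NULL,
                        rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1L] < 0)
    stop("ODE integration failed (lsoda istate = ", diagn[1L], ") for ",
         "conditions: AS0 = ", conditions$AS0, " M, FlBA0 = ",
         conditions$FlBA0, " M, O2 = ", conditions$O2, " M, nucleophile0 = ",
         conditions$nucleophile0, " M, duration = ", conditions$duration, " s")
  out <- as.data.frame(sol)
  names(out) <- c("time_s", species_names)
  for (nm in species_names) out[[nm]] <- pmax(out[[nm]], 0)
  structure(out, class = c("hno_trajectory", "data.frame"),
            rates = rates, conditions = conditions)
}

#' Conservation residuals of a trajectory
#'
#' Checks the two bookkeeping identities of the network under clamped O2,
#' unit donor yield and no peroxynitrite self-decomposition: every HNO
#' equivalent released by the donor must be found in the HNO, ONOO-,
#' probe-derived NO2-, adduct or (twice) N2O pools, and the fluorophore
#' pool FlBA + FlOH must stay at its initial value.
#'
#' @param trajectory A `hno_trajectory` from [integrate_full_model()].
#' @return Named numeric vector with the maximum absolute residual of each
#'   identity, in M: `nitrogen` and `fluorophore`.
#' @export
conservation_errors <- function(trajectory) {
  cond <- attr(trajectory, "conditions")
  released <- cond$AS0 - trajectory$AS
  found <- trajectory$HNO + trajectory$ONOO + trajectory$NO2 +
    trajectory$adduct + 2 * trajectory$N2O
  c(nitrogen = max(abs(cond$hno_yield * released - found)),
    fluorophore = max(abs(trajectory$FlBA + trajectory$FlOH - cond$FlBA0)))
}

#' Partition of HNO consumption among its loss channels
#'
#' Splits the HNO consumed over a trajectory among the three loss channels
#' (reaction with O2, reaction with the scavenger, dimerization) by exact
#' product bookkeeping: the adduct pool counts the scavenger channel, twice
#' the N2O pool counts dimerization, and the remainder of released-minus-
#' standing HNO is the O2 channel. Used to quantify how negligible the HNO
#' dimerization channel is at assay concentrations.
#'
#' @param trajectory A `hno_trajectory` from [integrate_full_model()].
#' @return Named numeric vector of fractions (`O2`, `nucleophile`,
#'   `dimerization`) summing to 1.
#' @examples
#' tr <- integrate_full_model(rate_constants(), experiment_conditions())
#' flux_partition(tr)   # dimerization is a ~1% channel at reference conditions
#' @export
flux_partition <- function(trajectory) {
  cond <- attr(trajectory, "conditions")
  n <- nrow(trajectory)
  released <- cond$hno_yield * (cond$AS0 - trajectory$AS[n])
  consumed <- released - trajectory$HNO[n]
  nuc_ch <- trajectory$adduct[n]
  dim_ch <- 2 * trajectory$N2O[n]
  o2_ch <- consumed - nuc_ch - dim_ch
  if (consumed <= 0)
    stop("no HNO was consumed over this trajectory; flux partition undefined")
  fr <- c(O2 = o2_ch, nucleophile = nuc_ch, dimerization = dim_ch) / consumed
  fr
}

#' Write a trajectory as tidy CSV
#'
#' One row per time point and species, columns `time_s`, `species`,
#' `concentration_M`.
#'
#' @param trajectory A `hno_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  long <- do.call(rbind, lapply(species_names, function(sp) {
    data.frame(time_s = trajectory$time_s, species = sp,
               concentration_M = trajectory[[sp]])
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
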