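# Deterministic seed splitting: trace i of a series gets
# (master + 104729 * i) mod (2^31 - 1), i = 0 for the control and then
# concentration-major, replicate-minor for the inhibited traces.
child_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 104729 * i) %% 2147483647)
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

absorbance_490 <- function(trajectory, optics) {
  optics$baseline + optics$path_length *
    (optics$epsilon_FlOH_490 * trajectory$FlOH +
       optics$epsilon_FlBA_490 * trajectory$FlBA)
}

new_kinetic_trace <- function(time_s, absorbance, metadata) {
  structure(data.frame(time_s = time_s, absorbance_490 = absorbance),
            class = c("kinetic_trace", "data.frame"),
            metadata = metadata)
}

#' Simulate one spectrophotometric kinetic trace
#'
#' Emulates a single kinetic run of the competition assay: the full network
#' is integrated, the fluorescein build-up is mapped to absorbance at 490
#' nm by the Beer-Lambert optics model, and additive Gaussian instrument
#' noise is applied. A given `seed` always reproduces the identical trace;
#' with `noise_sd = 0` the trace is exactly the deterministic optics
#' transform of the ODE trajectory.
#'
#' @param rates A [rate_constants()] object (set `k_nucleophile` and
#'   `conditions$nucleophile0` for an inhibited run).
#' @param conditions An [experiment_conditions()] object.
#' @param optics An [optics_model()] object.
#' @param sampling Sampling interval, s (default 5 s, a typical diode-array
#'   kinetic cycle time).
#' @param seed Integer seed for the noise draw; `NULL` uses the current RNG
#'   stream.
#' @return A `kinetic_trace`: data frame with columns `time_s` and
#'   `absorbance_490`, with run metadata attached as an attribute.
#' @examples
#' tr <- simulate_trace(rate_constants(), experiment_conditions(),
#'                      optics_model(noise_sd = 0))
#' head(tr)
#' @export
simulate_trace <- function(rates, conditions, optics = optics_model(),
                           sampling = 5, seed = NULL) {
  if (sampling <= 0) stop("'sampling' interval must be > 0")
  rates <- as_rate_constants(rates)
  conditions <- as_experiment_conditions(conditions)
  optics <- as_optics_model(optics)
  times <- seq(0, conditions$duration, by = sampling)
  traj <- integrate_full_model(rates, conditions, time_grid = times)
  a <- absorbance_490(traj, optics)
  a <- add_noise(a, optics$noise_sd, seed)
  new_kinetic_trace(times, a, list(
    nucleophile_conc = conditions$nucleophile0,
    is_control = conditions$nucleophile0 == 0 || rates$k_nucleophile == 0,
    replicate = 1L, seed = seed, compound = NA_character_))
}

add_noise <- function(a, noise_sd, seed) {
  if (noise_sd <= 0) return(a)
  noise <- if (is.null(seed)) stats::rnorm(length(a), 0, noise_sd)
  else with_seed(seed, stats::rnorm(length(a), 0, noise_sd))
  a + noise
}

#' @export
print.kinetic_trace <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf(
    "Kinetic trace at 490 nm: %d samples over %g s (%s, [nuc] = %.4g uM)\n",
    nrow(x), max(x$time_s),
    if (isTRUE(md$is_control)) "control" else "inhibited",
    md$nucleophile_conc * 1e6))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Default scavenger concentration grid
#'
#' Picks scavenger concentrations so that the expected inhibition statistic
#' `v0/vi - 1` lands on the target values (default 0.3 to 3, a range over
#' which the competition line is both measurable and far from complete
#' suppression of the probe channel), given the anticipated rate constant.
#'
#' @param k_true Anticipated second-order scavenger rate constant, 1/(M s).
#' @param conditions An [experiment_conditions()] object (supplies `[O2]`).
#' @param rates A [rate_constants()] object (supplies `k_O2`).
#' @param targets Target values of `v0/vi - 1`.
#' @return Scavenger concentrations in M.
#' @export
default_conc_grid <- function(k_true, conditions = experiment_conditions(),
                              rates = rate_constants(),
                              targets = c(0.3, 0.75, 1.5, 3)) {
  if (k_true <= 0) stop("'k_true' must be > 0")
  targets * rates$k_O2 * conditions$O2 / k_true
}

#' Generate a synthetic competition series
#'
#' Produces the full data set of one rate-constant determination: a control
#' trace without scavenger plus `replicates` noisy traces at each scavenger
#' concentration, all generated from the full network model with `k_true`
#' as ground truth. Per-trace seeds are derived deterministically from the
#' master seed, so regeneration under the same seed is bit-identical. The
#' deterministic trajectory is integrated once per distinct concentration
#' and shared across replicates.
#'
#' @param k_true Ground-truth second-order scavenger rate constant, 1/(M s).
#' @param nucleophile_concs Distinct positive scavenger concentrations, M.
#'   Default: [default_conc_grid()] for `k_true`.
#' @param replicates Replicate traces per concentration (default 3,
#'   mirroring determination in at least three independent runs).
#' @param conditions,optics Shared run conditions and readout model.
#' @param seed Master seed.
#' @param compound Optional compound label carried in trace metadata.
#' @param base_rates Network rate constants other than the scavenger
#'   channel.
#' @return A `competition_series`: list with elements `control`
#'   (a `kinetic_trace`), `inhibited` (list of `kinetic_trace`),
#'   `conditions`, `optics`, `rates_true`, `nucleophile_concs`,
#'   `replicates`, `seed`, `compound`.
#' @examples
#' ser <- generate_series(2.2e3, replicates = 2, seed = 42,
#'                        optics = optics_model(noise_sd = 0))
#' length(ser$inhibited)  # 2 replicates x 4 concentrations
#' @export
generate_series <- function(k_true,
                            nucleophile_concs = NULL,
                            replicates = 3,
                            conditions = experiment_conditions(),
                            optics = optics_model(),
                            seed = 1,
                            compound = NA_character_,
                            base_rates = rate_constants()) {
  conditions <- as_experiment_conditions(conditions)
  optics <- as_optics_model(optics)
  base_rates <- as_rate_constants(base_rates)
  if (is.null(nucleophile_concs))
    nucleophile_concs <- default_conc_grid(k_true, conditions, base_rates)
  if (length(nucleophile_concs) == 0)
    stop("'nucleophile_concs' must contain at least one concentration")
  if (any(nucleophile_concs <= 0) ||
      anyDuplicated(nucleophile_concs) > 0)
    stop("'nucleophile_concs' must be distinct and > 0")
  if (replicates < 1) stop("'replicates' must be >= 1")
  if (k_true < 0) stop("'k_true' must be >= 0")

  rates_true <- base_rates
  rates_true$k_nucleophile <- k_true
  sampling <- 5

  cond0 <- conditions
  cond0$nucleophile0 <- 0
  control <- simulate_trace(base_rates, cond0, optics, sampling,
                            seed = child_seed(seed, 0))
  md <- attr(control, "metadata"); md$compound <- compound
  attr(control, "metadata") <- md

  inhibited <- vector("list", length(nucleophile_concs) * replicates)
  i <- 0L
  for (j in seq_along(nucleophile_concs)) {
    cond_j <- conditions
    cond_j$nucleophile0 <- nucleophile_concs[j]
    times <- seq(0, cond_j$duration, by = sampling)
    traj <- integrate_full_model(rates_true, cond_j, time_grid = times)
    a0 <- absorbance_490(traj, optics)
    for (r in seq_len(replicates)) {
      i <- i + 1L
      a <- add_noise(a0, optics$noise_sd, child_seed(seed, i))
      inhibited[[i]] <- new_kinetic_trace(times, a, list(
        nucleophile_conc = nucleophile_concs[j],
        is_control = FALSE, replicate = r,
        seed = child_seed(seed, i), compound = compound))
    }
  }
  structure(list(control = control, inhibited = inhibited,
                 conditions = conditions, optics = optics,
                 rates_true = rates_true,
                 nucleophile_concs = nucleophile_concs,
                 replicates = as.integer(replicates),
                 seed = seed, compound = compound),
            class = "competition_series")
}

#' @export
print.competition_series <- function(x, ...) {
  cat(sprintf(
    "Competition series%s: control + %d traces (%d concentrations x %d replicates)\n",
    if (is.na(x$compound)) "" else paste0(" [", x$compound, "]"),
    length(x$inhibited), length(x$nucleophile_concs), x$replicates))
  cat(sprintf("  ground truth k_nucleophile = %.4g 1/(M s), master seed %s\n",
              x$rates_true$k_nucleophile, format(x$seed)))
  cat("  [nucleophile] grid (uM):",
      paste(signif(x$nucleophile_concs * 1e6, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Rate constants and computed barriers of the studied C-nucleophiles
#'
#' The packaged compound table of the thirteen cyclic C-nucleophiles:
#' identity, measured second-order HNO rate constant (1/(M s)) and computed
#' activation barrier of the HNO addition (kJ/mol). Rate constants for
#' compounds 3, 10 and 11 and the barrier for compound 6 were reported only
#' in tabular/graphical form not carried by this package and are `NA` here,
#' with the `k_source`/`barrier_source` columns saying so.
#'
#' @return Data frame with columns `compound_id`, `name`, `k_M_per_s`,
#'   `barrier_kJ_mol`, `k_source`, `barrier_source`.
#' @examples
#' hno_compounds()
#' @export
hno_compounds <- function() {
  path <- system.file("extdata", "hno_compounds.csv",
                      package = "hnokinetics", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(compound_id = "integer", name = "character",
                                 k_M_per_s = "numeric",
                                 barrier_kJ_mol = "numeric",
                                 k_source = "character",
                                 barrier_source = "character"))
}
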