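#' Convert micromolar to molar
#'
#' All internal computation in hnokinetics is carried out in SI molar units
#' (M, s); this helper keeps user code free of hand-written `1e-6` factors
#' when entering the micromolar concentrations in which bench work on HNO
#' donors is usually expressed.
#'
#' @param x Concentration(s) in micromolar.
#' @return Concentration(s) in molar.
#' @examples
#' uM(20)   # 2e-05 M, a typical Angeli's salt working concentration
#' @export
uM <- function(x) x * 1e-6

#' Kinetic rate constants of the HNO competition network
#'
#' Bundles the rate constants of every reaction channel in the donor/probe
#' network: first-order Angeli's salt decomposition (`k_AS`), the
#' second-order HNO + O2 reaction producing peroxynitrite (`k_O2`), the
#' peroxynitrite + boronate probe reaction (`k_FlBA`), spontaneous HNO
#' dimerization to N2O (`k_dim`), and the HNO + scavenger reaction whose
#' rate constant the competition experiment is designed to determine
#' (`k_nucleophile`, zero when no scavenger is present).
#'
#' Defaults are the reference values of the measurement system:
#' `k_AS = 8.0e-4` 1/s, `k_O2 = 1.8e4` 1/(M s), `k_FlBA = 1e6` 1/(M s),
#' `k_dim = 8e6` 1/(M s). An optional first-order peroxynitrite
#' self-decomposition channel (`k_onoo_decay`, default 0 1/s) is provided
#' for sensitivity analysis only; the competition model proper treats the
#' probe as the only peroxynitrite sink.
#'
#' @param k_AS First-order donor decomposition rate constant, 1/s.
#' @param k_O2 Second-order HNO + O2 rate constant, 1/(M s).
#' @param k_FlBA Second-order ONOO- + probe rate constant, 1/(M s).
#' @param k_dim Second-order HNO dimerization rate constant, 1/(M s),
#'   entering the rate law as d\[HNO\]/dt = -2 k_dim \[HNO\]^2.
#' @param k_nucleophile Second-order HNO + scavenger rate constant, 1/(M s).
#' @param k_onoo_decay Optional first-order ONOO- decay, 1/s (default 0).
#' @return An object of class `rate_constants`.
#' @examples
#' rate_constants()                        # reference network, no scavenger
#' rate_constants(k_nucleophile = 2.2e3)   # with a scavenger channel
#' @export
rate_constants <- function(k_AS = 8.0e-4,
                           k_O2 = 1.8e4,
                           k_FlBA = 1e6,
                           k_dim = 8e6,
                           k_nucleophile = 0,
                           k_onoo_decay = 0) {
  rc <- list(k_AS = k_AS, k_O2 = k_O2, k_FlBA = k_FlBA,
             k_dim = k_dim, k_nucleophile = k_nucleophile,
             k_onoo_decay = k_onoo_decay)
  for (nm in names(rc)) {
    v <- rc[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("rate constant '", nm, "' must be a single non-negative number")
  }
  structure(rc, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("HNO network rate constants:\n")
  cat(sprintf("  k_AS          = %.3g 1/s\n", x$k_AS))
  cat(sprintf("  k_O2          = %.3g 1/(M s)\n", x$k_O2))
  cat(sprintf("  k_FlBA        = %.3g 1/(M s)\n", x$k_FlBA))
  cat(sprintf("  k_dim         = %.3g 1/(M s)\n", x$k_dim))
  cat(sprintf("  k_nucleophile = %.3g 1/(M s)\n", x$k_nucleophile))
  if (x$k_onoo_decay > 0)
    cat(sprintf("  k_onoo_decay  = %.3g 1/s\n", x$k_onoo_decay))
  invisible(x)
}

#' Experimental conditions of a kinetic run
#'
#' Initial concentrations, optical path, run length and bookkeeping flags
#' for one spectrophotometric kinetic experiment. Defaults reproduce the
#' reference assay: 20 uM Angeli's salt, 25 uM FlBA probe, 225 uM dissolved
#' O2, a 600 s observation window, 1 cm cuvette, pH 7.4.
#'
#' `o2_clamped = TRUE` treats dissolved oxygen as a fixed reservoir, the
#' standard assumption of the competition analysis (at most ~9% of the 225
#' uM O2 pool can ever be consumed by 20 uM donor); set it to `FALSE` to
#' let O2 deplete dynamically in sensitivity checks. `hno_yield` is the
#' number of HNO equivalents released per donor molecule (unit yield by
#' default, per standard Angeli's salt chemistry).
#'
#' @param AS0 Initial Angeli's salt concentration, M.
#' @param FlBA0 Initial boronate probe concentration, M.
#' @param O2 Dissolved oxygen concentration, M.
#' @param nucleophile0 Scavenger concentration, M.
#' @param o2_clamped Logical; hold \[O2\] constant during integration.
#' @param duration Observation window, s.
#' @param path_length Cuvette path length, cm.
#' @param hno_yield HNO equivalents released per donor molecule, in (0, 1].
#' @param temperature_label,pH_label Metadata strings (not used in any
#'   computation).
#' @return An object of class `experiment_conditions`.
#' @examples
#' experiment_conditions()                       # reference conditions
#' experiment_conditions(nucleophile0 = uM(500)) # with 0.5 mM scavenger
#' @export
experiment_conditions <- function(AS0 = 20e-6,
                                  FlBA0 = 25e-6,
                                  O2 = 225e-6,
                                  nucleophile0 = 0,
                                  o2_clamped = TRUE,
                                  duration = 600,
                                  path_length = 1,
                                  hno_yield = 1,
                                  temperature_label = "25 C",
                                  pH_label = "pH 7.4") {
  for (nm in c("AS0", "FlBA0", "O2", "nucleophile0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("'", nm, "' must be a single non-negative concentration in M")
  }
  if (!is.numeric(duration) || duration <= 0) stop("'duration' must be > 0")
  if (!is.numeric(path_length) || path_length <= 0)
    stop("'path_length' must be > 0")
  if (!is.numeric(hno_yield) || hno_yield <= 0 || hno_yield > 1)
    stop("'hno_yield' must be in (0, 1]")
  structure(list(AS0 = AS0, FlBA0 = FlBA0, O2 = O2,
                 nucleophile0 = nucleophile0,
                 o2_clamped = isTRUE(o2_clamped),
                 duration = duration, path_length = path_length,
                 hno_yield = hno_yield,
                 temperature_label = temperature_label,
                 pH_label = pH_label),
            class = "experiment_conditions")
}

#' @export
print.experiment_conditions <- function(x, ...) {
  cat("Kinetic run conditions (", x$pH_label, ", ", x$temperature_label,
      "):\n", sep = "")
  cat(sprintf("  [AS]0  = %.4g uM   [FlBA]0 = %.4g uM\n",
              x$AS0 * 1e6, x$FlBA0 * 1e6))
  cat(sprintf("  [O2]   = %.4g uM (%s)   [nucleophile]0 = %.4g uM\n",
              x$O2 * 1e6, if (x$o2_clamped) "clamped" else "dynamic",
              x$nucleophile0 * 1e6))
  cat(sprintf("  duration = %g s, path length = %g cm, HNO yield = %g\n",
              x$duration, x$path_length, x$hno_yield))
  invisible(x)
}

#' Spectrophotometric readout model at 490 nm
#'
#' Beer-Lambert optics mapping species concentrations to the measured
#' absorbance at 490 nm, plus an additive Gaussian instrument-noise model.
#' Fluorescein (FlOH) dominates the 490 nm band; the intact probe absorbs
#' there only marginally (its own band lies at 378 nm), so
#' `epsilon_FlBA_490` defaults to zero. The fluorescein absorptivity is not
#' a determined quantity of the competition method -- every estimator in
#' this package uses rate ratios and is invariant to its value -- so the
#' default is a typical literature magnitude for the fluorescein dianion.
#'
#' @param epsilon_FlOH_490 Molar absorptivity of fluorescein at 490 nm,
#'   1/(M cm).
#' @param epsilon_FlBA_490 Residual probe absorptivity at 490 nm, 1/(M cm).
#' @param path_length Optical path length, cm.
#' @param noise_sd Standard deviation of additive Gaussian absorbance
#'   noise, AU.
#' @param baseline Constant baseline absorbance, AU.
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(epsilon_FlOH_490 = 7.5e4,
                         epsilon_FlBA_490 = 0,
                         path_length = 1,
                         noise_sd = 2e-3,
                         baseline = 0) {
  if (epsilon_FlOH_490 < 0 || epsilon_FlBA_490 < 0)
    stop("molar absorptivities must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (path_length <= 0) stop("'path_length' must be > 0")
  structure(list(epsilon_FlOH_490 = epsilon_FlOH_490,
                 epsilon_FlBA_490 = epsilon_FlBA_490,
                 path_length = path_length,
                 noise_sd = noise_sd,
                 baseline = baseline),
            class = "optics_model")
}

#' @export
print.optics_model <- function(x, ...) {
  cat(sprintf(
    "490 nm optics: eps(FlOH) = %.3g, eps(FlBA) = %.3g 1/(M cm), l = %g cm\n",
    x$epsilon_FlOH_490, x$epsilon_FlBA_490, x$path_length))
  cat(sprintf("  baseline = %g AU, noise sd = %g AU\n", x$baseline, x$noise_sd))
  invisible(x)
}

# internal: accept either a constructed object or a bare list with the same
# fields (e.g. deserialized from a JSON config) and re-validate it
as_rate_constants <- function(x) {
  if (inherits(x, "rate_constants")) return(x)
  do.call(rate_constants, x[intersect(names(x), names(formals(rate_constants)))])
}

as_experiment_conditions <- function(x) {
  if (inherits(x, "experiment_conditions")) return(x)
  do.call(experiment_conditions,
          x[intersect(names(x), names(formals(experiment_conditions)))])
}

as_optics_model <- function(x) {
  if (inherits(x, "optics_model")) return(x)
  do.call(optics_model, x[intersect(names(x), names(formals(optics_model)))])
}
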