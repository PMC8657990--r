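#' Configuration of an end-to-end reproduction run
#'
#' Bundles everything [run_reproduction()] needs: assay conditions, network
#' rate constants, readout model, the targets used to build per-compound
#' scavenger grids, replicate count, noise level and master seed. The
#' default configuration performs the headline noiseless reproduction:
#' every compound with a measured rate constant is re-simulated with that
#' value as ground truth and re-estimated by the competition-slope method.
#'
#' @param conditions,rates,optics Component configurations; see
#'   [experiment_conditions()], [rate_constants()], [optics_model()].
#' @param conc_targets Targets of `v0/vi - 1` for [default_conc_grid()].
#' @param replicates Replicates per concentration.
#' @param noise_sd Absorbance noise for the run, AU; overrides
#'   `optics$noise_sd` (default 0: the deterministic reproduction mode).
#' @param master_seed Integer master seed; recorded in all outputs.
#' @param compounds Compound table (default [hno_compounds()]).
#' @param output_dir Directory for the JSON report, or `NULL` to skip
#'   writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(conditions = experiment_conditions(),
                       rates = rate_constants(),
                       optics = optics_model(),
                       conc_targets = c(0.3, 0.75, 1.5, 3),
                       replicates = 3,
                       noise_sd = 0,
                       master_seed = 1,
                       compounds = hno_compounds(),
                       output_dir = NULL) {
  optics <- as_optics_model(optics)
  optics$noise_sd <- noise_sd
  structure(list(conditions = as_experiment_conditions(conditions),
                 rates = as_rate_constants(rates),
                 optics = optics,
                 conc_targets = conc_targets,
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd,
                 master_seed = as.integer(master_seed),
                 compounds = compounds,
                 output_dir = output_dir),
            class = "run_config")
}

# fold-ratio pairs reported by the study: each entry is (numerator compound,
# reference compound)
fold_ratio_pairs <- list(c(4L, 1L), c(7L, 1L), c(2L, 1L),
                         c(5L, 4L), c(8L, 4L), c(9L, 4L))

#' End-to-end reproduction of the competition-kinetics study
#'
#' Runs the complete pipeline at desk scale: (1) recover the donor
#' decomposition constant from a synthetic control trace; (2) for every
#' compound in the table with a measured rate constant, generate a
#' synthetic competition series with that value as ground truth and
#' recover it by the competition-slope method; (3) form the nearest-integer
#' fold ratios between recovered constants for the structurally related
#' pairs discussed in the study; (4) fit the barrier-vs-log10(k) line on
#' the recovered constants. Deterministic for a fixed master seed; the
#' report embeds the seed, the configuration and a hash binding the two.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `reproduction_report` (list; see the `schema` element), also
#'   written to `config$output_dir/report.json` when an output directory
#'   is configured.
#' @examples
#' \donttest{
#' rep <- run_reproduction(run_config(compounds = hno_compounds()[c(1, 4), ]))
#' rep$fold_ratios
#' }
#' @export
run_reproduction <- function(config = run_config(), quiet = FALSE) {
  if (!inherits(config, "run_config")) stop("'config' must be a run_config")
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("reproduction stage '", name, "' failed: ", conditionMessage(e),
           "\n  (master_seed = ", config$master_seed,
           ", noise_sd = ", config$noise_sd,
           ", replicates = ", config$replicates, ")", call. = FALSE)
    })
  }

  # stage 1: donor constant from a synthetic control trace
  kas <- stage("k_AS recovery", {
    say("k_AS", "simulating control trace, seed %d", config$master_seed)
    tr <- simulate_trace(config$rates, config$conditions, config$optics,
                         seed = child_seed(config$master_seed, 0))
    ir <- initial_rate(tr, config$optics)
    est <- estimate_k_as(ir, config$conditions$AS0)
    list(k_AS_true = config$rates$k_AS, k_AS_hat = as.numeric(est),
         se = attr(est, "se"), v0_hat = ir$rate,
         hno_flux_uM_per_s = hno_flux(config$rates$k_AS,
                                      config$conditions$AS0) * 1e6)
  })
  say("k_AS", "recovered %.4g 1/s (truth %.4g)", kas$k_AS_hat, kas$k_AS_true)

  # stage 2: per-compound simulate-then-recover
  cmp <- config$compounds
  cmp <- cmp[is.finite(cmp$k_M_per_s) & cmp$k_M_per_s > 0, , drop = FALSE]
  recov <- stage("compound recovery", {
    rows <- lapply(seq_len(nrow(cmp)), function(i) {
      id <- cmp$compound_id[i]; k_true <- cmp$k_M_per_s[i]
      seed_i <- child_seed(config$master_seed, 1000 + id)
      say("recover", "compound %d (%s): k_true = %.3g, seed %d",
          id, cmp$name[i], k_true, seed_i)
      ser <- generate_series(
        k_true,
        nucleophile_concs = default_conc_grid(k_true, config$conditions,
                                              config$rates,
                                              config$conc_targets),
        replicates = config$replicates,
        conditions = config$conditions, optics = config$optics,
        seed = seed_i, compound = as.character(id),
        base_rates = config$rates)
      est <- estimate_k_nucleophile(ser)
      data.frame(compound_id = id, name = cmp$name[i], k_true = k_true,
                 k_hat = est$k_nucleophile_hat, k_se = est$k_se,
                 rel_error = est$k_nucleophile_hat / k_true - 1,
                 seed = seed_i)
    })
    do.call(rbind, rows)
  })

  # stage 3: fold ratios of recovered constants (nearest integer, the
  # convention in which the study quotes them)
  folds <- stage("fold ratios", {
    rows <- lapply(fold_ratio_pairs, function(p) {
      i <- match(p[1], recov$compound_id); j <- match(p[2], recov$compound_id)
      if (is.na(i) || is.na(j)) return(NULL)
      ratio <- recov$k_hat[i] / recov$k_hat[j]
      data.frame(numerator = p[1], reference = p[2],
                 ratio = ratio, fold = round(ratio))
    })
    do.call(rbind, rows)
  })
  if (!quiet && !is.null(folds))
    say("folds", "%s", paste(sprintf("k%d/k%d = %d", folds$numerator,
                                     folds$reference, folds$fold),
                             collapse = ", "))

  # stage 4: linear free-energy fit on the *recovered* constants
  tab <- merge(recov[, c("compound_id", "k_hat")],
               config$compounds[, c("compound_id", "barrier_kJ_mol")],
               by = "compound_id")
  names(tab)[names(tab) == "k_hat"] <- "k_M_per_s"
  if (sum(is.finite(tab$k_M_per_s) & is.finite(tab$barrier_kJ_mol)) >= 3) {
    sar <- stage("barrier fit", {
      fit <- fit_barrier_loglinear(tab)
      list(slope = fit$slope, intercept = fit$intercept,
           r_squared = fit$r_squared, n = fit$n)
    })
    say("sar", "barrier fit: slope %.3f kJ/mol per log10 unit, R^2 = %.3f",
        sar$slope, sar$r_squared)
  } else {
    sar <- NULL
    say("sar", "fewer than 3 recovered compounds with barriers; fit skipped")
  }

  cfg_json <- as.character(jsonlite::toJSON(unclass_deep(config),
                                            auto_unbox = TRUE, digits = NA))
  report <- structure(list(
    schema = "hnokinetics/reproduction-report-1",
    master_seed = config$master_seed,
    config_hash = fnv1a32(cfg_json),
    config = unclass_deep(config),
    k_as = kas,
    compounds = recov,
    fold_ratios = folds,
    barrier_fit = sar), class = "reproduction_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass_deep(report),
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    say("report", "written to %s", file.path(config$output_dir, "report.json"))
  }
  report
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("Reproduction report (seed ", x$master_seed, ", config ",
      x$config_hash, ")\n", sep = "")
  cat(sprintf("  k_AS: recovered %.4g 1/s (truth %.4g); HNO flux %.3g uM/s\n",
              x$k_as$k_AS_hat, x$k_as$k_AS_true, x$k_as$hno_flux_uM_per_s))
  cat("  Recovered rate constants:\n")
  print(x$compounds[, c("compound_id", "k_true", "k_hat", "rel_error")],
        row.names = FALSE, digits = 4)
  if (!is.null(x$fold_ratios)) {
    cat("  Fold ratios (nearest integer):",
        paste(sprintf("k%d/k%d = %d", x$fold_ratios$numerator,
                      x$fold_ratios$reference, x$fold_ratios$fold),
              collapse = ", "), "\n")
  }
  if (!is.null(x$barrier_fit))
    cat(sprintf("  Barrier fit: slope %.3f kJ/mol per log10(k), R^2 = %.3f (n = %d)\n",
                x$barrier_fit$slope, x$barrier_fit$r_squared, x$barrier_fit$n))
  invisible(x)
}
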